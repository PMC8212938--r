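#' Default configuration of the family-cataloguing pipeline
#'
#' @return Named list of all pipeline parameters and their defaults.
#' @export
default_pipeline_config <- function() {
  list(simulate = FALSE, sim = list(), fasta = NULL, coordinates = NULL,
       allowed_heptapeptides = wrky_heptapeptides(), strict_mode = FALSE,
       max_zf_gap = 60, distance_model = "p_distance",
       gap_open = -10, gap_extend = -1, n_boot = 0, seed = 1,
       max_within_distance = 0.45, prefix = "TaWRKY", references = NULL,
       comparators = c(rice = 103, maize = 119))
}

#' Run the full family-cataloguing pipeline
#'
#' Orchestrates scan -> isoform collapse -> progressive alignment ->
#' neighbor-joining tree (optionally with bootstrap supports) -> homeolog
#' group inference -> nomenclature -> group classification -> summary
#' statistics, as one reproducible run. Inputs are either a protein FASTA
#' (plus optional coordinate table) or, with `simulate = TRUE`, a synthetic
#' proteome from [simulate_proteome()] configured via the `sim` entry.
#'
#' @param config a named list (or path to a YAML file) overriding entries
#'   of [default_pipeline_config()]. Recognised entries include `simulate`,
#'   `sim` (arguments to [sim_config()]), `fasta`, `coordinates`,
#'   `allowed_heptapeptides`, `strict_mode`, `max_zf_gap`,
#'   `distance_model`, `gap_open`, `gap_extend`, `n_boot`, `seed`,
#'   `prefix`, `references` (a labelled reference FASTA whose headers carry
#'   `|subgroup` suffixes, used to resolve group II subgroups),
#'   `comparators`.
#' @param output_dir if given, the catalog TSV, stats JSON, newick tree and
#'   run manifest are written there.
#' @param quiet suppress progress messages.
#' @return An object of class `family_catalog`: list with `records`,
#'   `scan`, `copies`, `alignment`, `tree`, `groups`, `calls`, `stats`,
#'   `simulation` (when simulated) and `manifest`. Rerunning with the same
#'   configuration and seed reproduces the catalog exactly.
#' @export
run_pipeline <- function(config = list(), output_dir = NULL, quiet = TRUE) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  defs <- default_pipeline_config()
  unknown <- setdiff(names(config), names(defs))
  if (length(unknown)) stop("unknown config entries: ", paste(unknown, collapse = ", "))
  defaults_applied <- setdiff(names(defs), names(config))
  cfg <- modifyList(defs, config)
  if (!is.null(config[["sim"]])) cfg$sim <- config[["sim"]]  # keep a sim_config intact
  if (isTRUE(cfg$strict_mode) && !"allowed_heptapeptides" %in% names(config)) {
    cfg$allowed_heptapeptides <- wrky_heptapeptides(strict = TRUE)
  }
  say <- function(...) if (!quiet) message("[wrkycatalog] ", ...)

  simulation <- NULL
  if (isTRUE(cfg$simulate)) {
    say("simulating proteome")
    sim_cfg <- if (inherits(cfg$sim, "sim_config")) {
      cfg$sim
    } else {
      sim_args <- cfg$sim
      if (!"seed" %in% names(sim_args)) sim_args$seed <- cfg$seed
      do.call(sim_config, sim_args)
    }
    simulation <- simulate_proteome(sim_cfg)
    records <- simulation$records
    coords <- simulation$coordinates
  } else {
    if (is.null(cfg$fasta) || !file.exists(cfg$fasta)) {
      stop("stage input: FASTA file required when simulate = FALSE (got: ",
           cfg$fasta %||% "NULL", ")")
    }
    records <- read_protein_fasta(cfg$fasta)
    coords <- if (!is.null(cfg$coordinates)) read_coordinates(cfg$coordinates) else NULL
  }
  if (!is.null(coords)) records <- apply_coordinates(records, coords)

  say("scanning ", nrow(records), " records")
  scan <- scan_proteome(records, cfg$allowed_heptapeptides, cfg$max_zf_gap)
  if (nrow(scan$candidates) == 0) stop("stage scan: no WRKY family candidates found")
  copies <- collapse_isoforms(scan)

  say("aligning ", nrow(copies), " collapsed copies")
  seqs <- setNames(copies$sequence, copies$gene_id)
  if (length(seqs) < 3) stop("stage tree: need at least 3 collapsed copies")
  aln <- progressive_msa(seqs, gap_open = cfg$gap_open, gap_extend = cfg$gap_extend)
  # family-wide alignments can leave a pair of unrelated members with no
  # shared ungapped column; such saturated pairs take the maximal distance
  dm <- distance_from_alignment(aln, cfg$distance_model, on_empty = "max")
  tree <- neighbor_joining(dm)
  if (cfg$n_boot > 0) {
    say("bootstrapping (", cfg$n_boot, " replicates)")
    tree <- attach_bootstrap(aln, tree, n_reps = cfg$n_boot, seed = cfg$seed,
                             model = cfg$distance_model)
  }

  say("inferring homeolog groups")
  groups <- infer_groups(tree, copies, max_within_distance = cfg$max_within_distance)
  groups <- assign_names(groups, cfg$prefix)
  stats <- summary_stats(groups, comparators = cfg$comparators)

  say("classifying copies")
  calls <- classify_copies(copies, scan)
  if (!is.null(cfg$references)) {
    refs <- read_reference_fasta(cfg$references)
    joint <- c(seqs, setNames(refs$sequence, refs$id))
    jaln <- progressive_msa(joint, gap_open = cfg$gap_open, gap_extend = cfg$gap_extend)
    jtree <- neighbor_joining(distance_from_alignment(jaln, cfg$distance_model))
    labels <- setNames(refs$subgroup, refs$id)
    ii <- which(calls$group == "II")
    for (k in ii) {
      calls$group[k] <- resolve_subgroup(calls$gene_id[k], jtree, labels)$group
    }
  }

  manifest <- list(config = cfg[setdiff(names(cfg), "sim")],
                   sim = if (isTRUE(cfg$simulate)) unclass(simulation$truth$config) else NULL,
                   defaults_applied = defaults_applied,
                   package_version = as.character(utils::packageVersion("wrkycatalog")),
                   n_input_records = nrow(records))

  catalog <- structure(list(records = records, scan = scan, copies = copies,
                            alignment = aln, tree = tree, groups = groups,
                            calls = calls, stats = stats,
                            simulation = simulation, manifest = manifest),
                       class = "family_catalog")
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_catalog(catalog, file.path(output_dir, "catalog.tsv"))
    write_newick(tree, file.path(output_dir, "tree.nwk"))
    jsonlite::write_json(unclass_stats(stats),
                         file.path(output_dir, "stats.json"),
                         dataframe = "columns", auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, null = "null", digits = NA)
  }
  catalog
}

unclass_stats <- function(stats) {
  s <- unclass(stats)
  s$types <- as.data.frame(s$types)
  s
}

# Reference FASTA whose headers look like ">AtWRKY40|IIa": id before the
# pipe, subgroup label after it.
read_reference_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  hdr <- vapply(strsplit(names(ss), "[[:space:]]+"), `[`, character(1), 1)
  parts <- strsplit(hdr, "|", fixed = TRUE)
  bad <- lengths(parts) != 2
  if (any(bad)) stop("reference headers must be 'id|subgroup': ",
                     paste(utils::head(hdr[bad], 3), collapse = ", "))
  data.frame(id = vapply(parts, `[`, character(1), 1),
             subgroup = vapply(parts, `[`, character(1), 2),
             sequence = toupper(as.character(ss)), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' @export
print.family_catalog <- function(x, ...) {
  cat("WRKY family catalog\n")
  cat("  input records:     ", x$manifest$n_input_records, "\n")
  cat("  candidate records: ", nrow(x$scan$candidates), "\n")
  cat("  gene copies:       ", nrow(x$copies), "\n")
  cat("  genes (groups):    ", nrow(x$groups$groups), "\n")
  gt <- table(factor(sub("^II[a-e]$", "II", x$calls$group),
                     levels = c("I", "II", "III")))
  cat("  WRKY groups:        I =", gt[["I"]], " II =", gt[["II"]],
      " III =", gt[["III"]], "\n")
  invisible(x)
}

#' @export
summary.family_catalog <- function(object, ...) {
  object$stats
}
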