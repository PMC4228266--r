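# Orchestration: file-based configuration, end-to-end runs, reports.
# Config files are flat JSON key-value objects; every stochastic stage
# takes an explicit seed recorded in the run log.

read_config <- function(config) {
  if (is.character(config) && length(config) == 1L && file.exists(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (!is.list(config)) stop("config must be a list or a JSON file path",
                             call. = FALSE)
  config
}

config_get <- function(cfg, key, default = NULL, required = FALSE) {
  if (!is.null(cfg[[key]])) return(cfg[[key]])
  if (required) stop("config key missing: ", key, call. = FALSE)
  default
}

#' Run the ancestral-reconstruction stage from a configuration
#'
#' Validates the configuration (all inputs must resolve before any
#' computation starts), fits [asr()], samples alternate ancestors, and
#' writes ancestor FASTA, per-site posterior CSV, support summaries, an
#' NHX-annotated tree and a JSON run log to `out_dir`.
#'
#' Config keys: `alignment` (FASTA path), `tree` (Newick path), `out_dir`;
#' optional `model` ("LG"/"WAG"/"JTT", default LG), `gamma_k` (default 4),
#' `alpha` (number, default 1), `outgroup` (taxa), `optimize_lengths`
#' (default TRUE), `n_alternates` (default 0), `seed` (default 1).
#'
#' @param config list or JSON file path.
#' @return invisibly, a list with the `asr_fit`, alternate samples, and
#'   output paths.
#' @export
run_asr <- function(config) {
  cfg <- read_config(config)
  aln_path <- config_get(cfg, "alignment", required = TRUE)
  tree_path <- config_get(cfg, "tree", required = TRUE)
  out_dir <- config_get(cfg, "out_dir", required = TRUE)
  for (p in c(aln_path, tree_path))
    if (!file.exists(p)) stop("input not found: ", p, call. = FALSE)

  aln <- read_alignment(aln_path)
  tree <- ape::read.tree(tree_path)
  outgroup <- config_get(cfg, "outgroup")
  if (!is.null(outgroup)) {
    bad <- setdiff(outgroup, tree$tip.label)
    if (length(bad))
      stop("outgroup taxa absent from tree: ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  check_taxa(tree, rownames(aln))
  model <- subst_model(config_get(cfg, "model", "LG"),
                       alpha = config_get(cfg, "alpha", 1),
                       k = config_get(cfg, "gamma_k", 4))
  seed <- as.integer(config_get(cfg, "seed", 1L))

  fit <- asr(aln, tree, model, outgroup = outgroup,
             optimize_lengths = isTRUE(config_get(cfg, "optimize_lengths",
                                                  TRUE)))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(ancestors = file.path(out_dir, "ancestors.fasta"),
                posteriors = file.path(out_dir, "posteriors.csv"),
                support = file.path(out_dir, "support.csv"),
                tree = file.path(out_dir, "annotated.nhx"),
                log = file.path(out_dir, "run_log.json"))
  export_asr(fit, fasta = paths$ancestors, csv = paths$posteriors)
  sup <- data.frame(node = names(fit$supports),
                    mean_pp = vapply(fit$supports, `[[`, 0, "mean"),
                    var_pp = vapply(fit$supports, `[[`, 0, "variance"))
  utils::write.csv(sup, paths$support, row.names = FALSE)
  ann <- data.frame(node = names(fit$posteriors),
                    mean_pp = signif(sup$mean_pp, 6))
  annotate_tree(fit$tree, ann, path = paths$tree)

  n_alt <- as.integer(config_get(cfg, "n_alternates", 0L))
  alternates <- NULL
  if (n_alt > 0L) {
    alternates <- lapply(seq_along(fit$posteriors), function(i)
      sample_alternate_ancestors(fit$posteriors[[i]], n_alt,
                                 seed = seed + i, indels = fit$indels))
    names(alternates) <- names(fit$posteriors)
    alt_path <- file.path(out_dir, "alternate_ancestors.fasta")
    con <- file(alt_path, "w")
    for (nm in names(alternates))
      for (j in seq_len(n_alt))
        writeLines(c(paste0(">", nm, "_alt", j),
                     alternates[[nm]]$sequences[j]), con)
    close(con)
    paths$alternates <- alt_path
  }
  jsonlite::write_json(
    list(stage = "asr", seed = seed, model = model$name,
         alpha = if (!is.null(model$gamma)) model$gamma$alpha else NULL,
         n_taxa = n_tips(fit$tree), n_sites = fit$n_sites,
         loglik = fit$loglik, n_alternates = n_alt,
         config = cfg),
    paths$log, auto_unbox = TRUE, digits = NA)
  invisible(list(fit = fit, alternates = alternates, paths = paths))
}

#' Run the specificity stage from a configuration
#'
#' Reads PSPL array and (optionally) kinetics/velocity CSVs, builds
#' per-kinase specificity profiles (position-normalized, replicate
#' averaged, log2; fixed-S/T mixtures masked), +1 log-ratios and state
#' classifications, Michaelis-Menten fits, and writes CSV tables plus a
#' JSON report.
#'
#' Config keys: `pspl` (CSV: kinase, replicate, fixed_position,
#' fixed_residue, intensity), `out_dir`; optional `kinetics` (CSV:
#' peptide, kinase, acceptor, plus1, conc_uM, v0, enzyme_nM, replicate),
#' `velocities` (CSV: kinase, plus1, replicate, v0), `threshold`
#' (classification threshold, default 1).
#'
#' @param config list or JSON file path.
#' @return invisibly, a list with `profiles`, `ratios`, `states`, `fits`,
#'   and the report path.
#' @export
run_specificity <- function(config) {
  cfg <- read_config(config)
  pspl_path <- config_get(cfg, "pspl", required = TRUE)
  out_dir <- config_get(cfg, "out_dir", required = TRUE)
  if (!file.exists(pspl_path)) stop("input not found: ", pspl_path,
                                    call. = FALSE)
  threshold <- config_get(cfg, "threshold", 1)

  raw <- utils::read.csv(pspl_path, stringsAsFactors = FALSE)
  need <- c("kinase", "replicate", "fixed_position", "fixed_residue",
            "intensity")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("pspl csv lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(!is.finite(raw$intensity))
  if (length(bad))
    stop("malformed intensity in pspl csv row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  profiles <- list(); ratios <- list()
  for (kn in unique(raw$kinase)) {
    reps <- split(raw[raw$kinase == kn, ], raw$replicate[raw$kinase == kn])
    prof <- combine_replicates(lapply(reps, normalize_array))
    prof <- exclude_phosphoacceptor_rows(prof)
    profiles[[kn]] <- prof
    ratios[[kn]] <- plus1_log_ratio(prof)
  }
  states <- classify_state(unlist(ratios), threshold = threshold)
  names(states) <- names(ratios)

  prof_tab <- do.call(rbind, lapply(names(profiles), function(kn) {
    p <- profiles[[kn]]
    data.frame(kinase = kn,
               position = rep(rownames(p$log2), ncol(p$log2)),
               residue = rep(colnames(p$log2), each = nrow(p$log2)),
               log2_selectivity = as.vector(p$log2),
               masked = as.vector(p$mask))
  }))
  utils::write.csv(prof_tab, file.path(out_dir, "profiles.csv"),
                   row.names = FALSE)

  fits <- NULL
  kin_path <- config_get(cfg, "kinetics")
  if (!is.null(kin_path) && file.exists(kin_path)) {
    kin <- utils::read.csv(kin_path, stringsAsFactors = FALSE)
    fits <- lapply(split(kin, kin$peptide), function(d)
      fit_mm(d$conc_uM, d$v0, enzyme_nM = d$enzyme_nM[1],
             peptide = d$peptide[1], acceptor = d$acceptor[1],
             plus1 = d$plus1[1]))
    fit_tab <- do.call(rbind, lapply(fits, function(f)
      data.frame(peptide = f$peptide, plus1 = f$plus1, K_M = f$K_M,
                 k_cat = f$k_cat, efficiency = f$efficiency)))
    utils::write.csv(fit_tab, file.path(out_dir, "mm_fits.csv"),
                     row.names = FALSE)
  }

  vel_ratios <- NULL
  vel_path <- config_get(cfg, "velocities")
  if (!is.null(vel_path) && file.exists(vel_path)) {
    vel <- utils::read.csv(vel_path, stringsAsFactors = FALSE)
    vel_ratios <- lapply(split(vel, vel$kinase), function(d)
      ratiometric_specificity(d$v0[d$plus1 == "R"], d$v0[d$plus1 == "P"],
                              ids = c("+1R", "+1P")))
  }

  report <- list(
    stage = "specificity", threshold = threshold,
    plus1_log2_ratio = ratios,
    plus1_fold = lapply(ratios, function(r) 2^r),
    state = as.list(unclass(states)[seq_along(states)]),
    kinetics = if (is.null(fits)) "absent" else
      lapply(fits, function(f) list(peptide = f$peptide, K_M = f$K_M,
                                    k_cat = f$k_cat,
                                    efficiency = f$efficiency)),
    velocity_log2_ratio = if (is.null(vel_ratios)) NULL else
      lapply(vel_ratios, `[[`, "log2_ratio"))
  rp <- file.path(out_dir, "specificity_report.json")
  jsonlite::write_json(report, rp, auto_unbox = TRUE, digits = NA)
  invisible(list(profiles = profiles, ratios = ratios, states = states,
                 fits = fits, velocity_ratios = vel_ratios, report = rp))
}

#' Run the full pipeline on a fixture-style bundle
#'
#' End-to-end: ancestral reconstruction on the bundle's alignment and
#' tree, per-kinase PSPL profiles with +1 state classification, DFGx
#' extraction from tip and reconstructed ancestor sequences, and the
#' transition report. Accepts the in-memory bundle from
#' [generate_fixture_study()] or a directory written by it.
#'
#' @param bundle fixture bundle list, or a directory path containing
#'   `tree.nwk`, `alignment.fasta`, `pspl.csv`.
#' @param threshold classification threshold on |log2 ratio|.
#' @param model `subst_model` for the reconstruction.
#' @return list with `asr` (the `asr_fit`), `states` (named specificity
#'   states of the measured kinases), `ratios`, `dfgx` (per-node
#'   residues), `transitions` (branches where DFGx changes).
#' @export
run_pipeline <- function(bundle, threshold = 1,
                         model = subst_model("LG", alpha = 1, k = 4)) {
  if (is.character(bundle)) {
    dir <- bundle
    raw <- utils::read.csv(file.path(dir, "pspl.csv"),
                           stringsAsFactors = FALSE)
    pspl <- lapply(split(raw, raw$kinase), function(d)
      lapply(split(d, d$replicate), identity))
    bundle <- list(
      tree = ape::read.tree(file.path(dir, "tree.nwk")),
      alignment = read_alignment(file.path(dir, "alignment.fasta")),
      pspl = pspl)
  }
  fit <- asr(bundle$alignment, bundle$tree, model)

  ratios <- vapply(bundle$pspl, function(reps) {
    prof <- combine_replicates(lapply(reps, normalize_array))
    plus1_log_ratio(exclude_phosphoacceptor_rows(prof))
  }, numeric(1))
  states <- classify_state(ratios, threshold = threshold)
  names(states) <- names(ratios)

  # ungapped sequences: tips from the alignment, ancestors from the fit
  tipseq <- vapply(rownames(bundle$alignment), function(tx)
    paste(bundle$alignment[tx, ], collapse = ""), "")
  seqs <- c(tipseq, fit$ml_sequences)
  seqs <- vapply(seqs, function(s) gsub("-", "", s), "")
  dfgx <- map_dfgx_transitions(fit$tree, seqs)

  list(asr = fit, states = states, ratios = ratios,
       dfgx = dfgx$dfgx, transitions = dfgx$transitions,
       failed_dfgx = dfgx$failed)
}
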