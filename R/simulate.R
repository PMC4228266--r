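# Generators for every data type the pipeline consumes, with recorded
# ground truth so each stage can be validated by recovery tests.

#' Simulate a Yule tree
#'
#' Pure-birth tree with `n_taxa` leaves (via [ape::rphylo()]), rescaled so
#' the maximum root-to-tip path equals `height` substitutions/site.
#'
#' @param n_taxa number of leaves (>= 2).
#' @param birth_rate Yule birth rate.
#' @param seed integer seed.
#' @param height target tree height after rescaling (`NULL` keeps raw
#'   branch lengths).
#' @return rooted ape `phylo`; tips `t1..tn`.
#' @export
simulate_tree <- function(n_taxa, birth_rate = 1, seed = 1L, height = 0.5) {
  if (n_taxa < 2L) stop("n_taxa must be >= 2", call. = FALSE)
  set.seed(as.integer(seed))
  tr <- ape::rphylo(n_taxa, birth = birth_rate, death = 0)
  if (!is.null(height)) {
    h <- max(ape::node.depth.edgelength(tr)[seq_len(n_taxa)])
    tr$edge.length <- tr$edge.length * height / h
  }
  tr
}

# sample child states given parent states through matrix P (integer codes)
evolve_states <- function(parent, P) {
  child <- integer(length(parent))
  for (a in unique(parent)) {
    idx <- which(parent == a)
    child[idx] <- sample.int(20L, length(idx), replace = TRUE, prob = P[a, ])
  }
  child
}

#' Simulate sequence evolution along a tree
#'
#' Evolves amino-acid sequences under a reversible model with
#' discrete-gamma rate heterogeneity: the root sequence is drawn from the
#' equilibrium frequencies, each site is assigned a rate category uniformly
#' at random, and residues evolve along each branch with transition
#' probabilities \eqn{P(t r_k)}. Insertion/deletion events are modelled as
#' independent per-site binary presence/absence characters: every site is
#' present at the root and toggles state along a branch of length \eqn{t}
#' with probability \eqn{(1 - e^{-2 \rho t})/2} (rate \eqn{\rho} =
#' `indel_rate`). Absent sites appear as gaps. True ancestral sequences,
#' indel states and site categories are recorded.
#'
#' @param tree rooted ape `phylo`.
#' @param model a `subst_model`.
#' @param n_sites number of sites (>= 1).
#' @param indel_rate per-unit-branch-length toggle rate of the indel
#'   character (0 = no gaps).
#' @param seed integer seed.
#' @return Object of class `sim_evolution`: list with `alignment` (tip
#'   matrix, gaps as `-`), `truth` (list: `node_sequences` named character,
#'   gaps applied; `presence` node x site logical; `site_category`;
#'   `seed`), and `tree`.
#' @export
simulate_evolution <- function(tree, model, n_sites, indel_rate = 0,
                               seed = 1L) {
  if (n_sites < 1L) stop("n_sites must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))
  nt <- n_tips(tree)
  nn <- nt + tree$Nnode
  pi <- model$matrix$frequencies
  rates <- model_rates(model)
  K <- length(rates)
  cat_of <- sample.int(K, n_sites, replace = TRUE)

  states <- matrix(NA_integer_, nn, n_sites)
  present <- matrix(NA, nn, n_sites)
  rid <- root_id(tree)
  states[rid, ] <- sample.int(20L, n_sites, replace = TRUE, prob = pi)
  present[rid, ] <- TRUE

  po <- postorder_edges(tree)
  for (e in rev(seq_len(nrow(po$edge)))) {    # preorder: parents first
    par <- po$edge[e, 1]; ch <- po$edge[e, 2]
    t_e <- po$length[e]
    for (k in seq_len(K)) {
      idx <- which(cat_of == k)
      if (!length(idx)) next
      P <- transition_matrix(model, t_e, rates[k])
      states[ch, idx] <- evolve_states(states[par, idx], P)
    }
    p_flip <- (1 - exp(-2 * indel_rate * t_e)) / 2
    flip <- stats::runif(n_sites) < p_flip
    present[ch, ] <- xor(present[par, ], flip)
  }

  chars <- matrix(aa_alphabet[states], nn, n_sites)
  chars[!present] <- aa_gap
  node_seqs <- apply(chars, 1, paste, collapse = "")
  names(node_seqs) <- vapply(seq_len(nn), function(i) node_label(tree, i), "")
  aln <- chars[seq_len(nt), , drop = FALSE]
  rownames(aln) <- tree$tip.label

  structure(list(
    alignment = aln,
    tree = tree,
    truth = list(node_sequences = node_seqs, presence = present,
                 states = states, site_category = cat_of,
                 seed = as.integer(seed))),
    class = "sim_evolution")
}

#' Simulate a PSPL spot-intensity array
#'
#' Generates raw intensities for the full 182-mixture library from a known
#' position-specific preference matrix: the intensity of the mixture
#' fixing residue `a` at position `p` is
#' `scale * w[p, a] * lognormal(1, noise_cv)`; acceptor mixtures use
#' `acceptor_weights`. The lognormal noise has mean 1 and coefficient of
#' variation `noise_cv`.
#'
#' @param preference 9 x 20 positive matrix (rows `-5`..`+4`, columns
#'   [aa_alphabet]).
#' @param n_replicates number of replicate arrays.
#' @param noise_cv multiplicative noise CV (0 = noiseless).
#' @param seed integer seed.
#' @param acceptor_weights named positive weights for the S and T acceptor
#'   mixtures.
#' @param scale global intensity scale (arbitrary units).
#' @param kinase label carried into the arrays.
#' @return list of `n_replicates` raw-array data.frames (columns `kinase`,
#'   `replicate`, `fixed_position`, `fixed_residue`, `intensity`) with the
#'   truth in attribute `truth`.
#' @export
simulate_pspl <- function(preference, n_replicates = 2L, noise_cv = 0.1,
                          seed = 1L, acceptor_weights = c(S = 1, T = 1),
                          scale = 1000, kinase = "kinase1") {
  if (any(preference <= 0) || any(acceptor_weights <= 0))
    stop("preference values must be positive", call. = FALSE)
  set.seed(as.integer(seed))
  lib <- design_library()
  sdlog <- sqrt(log(1 + noise_cv^2))
  reps <- lapply(seq_len(n_replicates), function(r) {
    acc <- lib$fixed_position == "acceptor"
    w <- numeric(nrow(lib))
    w[acc] <- acceptor_weights[lib$fixed_residue[acc]]
    w[!acc] <- preference[cbind(lib$fixed_position[!acc],
                                lib$fixed_residue[!acc])]
    noise <- if (noise_cv > 0)
      stats::rlnorm(nrow(lib), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    else 1
    data.frame(kinase = kinase, replicate = r,
               fixed_position = lib$fixed_position,
               fixed_residue = lib$fixed_residue,
               intensity = scale * w * noise)
  })
  attr(reps, "truth") <- list(preference = preference,
                              acceptor_weights = acceptor_weights,
                              noise_cv = noise_cv, seed = as.integer(seed))
  reps
}

#' Simulate Michaelis-Menten velocity data
#'
#' \eqn{V_0 = k_{cat} [E] [S]/(K_M + [S])} with multiplicative lognormal
#' noise (mean 1, CV `noise_cv`); enzyme concentration in nM is converted
#' to uM so velocities are in uM/min.
#'
#' @param K_M uM; `k_cat` 1/min; `enzyme_nM` nM.
#' @param k_cat,enzyme_nM see above.
#' @param concs substrate concentrations, uM.
#' @param noise_cv multiplicative noise CV.
#' @param n_replicates replicates per concentration.
#' @param seed integer seed.
#' @return data.frame `conc_uM`, `v0` (uM/min), `enzyme_nM`, `replicate`,
#'   with attribute `truth`.
#' @export
simulate_kinetics <- function(K_M, k_cat, enzyme_nM = 10, concs,
                              noise_cv = 0.05, n_replicates = 1L,
                              seed = 1L) {
  stopifnot(K_M > 0, k_cat > 0, enzyme_nM > 0, all(concs > 0))
  set.seed(as.integer(seed))
  sdlog <- sqrt(log(1 + noise_cv^2))
  E_uM <- enzyme_nM / 1000
  out <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
    mu <- k_cat * E_uM * concs / (K_M + concs)
    noise <- if (noise_cv > 0)
      stats::rlnorm(length(concs), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    else 1
    data.frame(conc_uM = concs, v0 = mu * noise, enzyme_nM = enzyme_nM,
               replicate = r)
  }))
  attr(out, "truth") <- list(K_M = K_M, k_cat = k_cat,
                             enzyme_nM = enzyme_nM, noise_cv = noise_cv,
                             seed = as.integer(seed))
  out
}

# preference matrix with a planted +1 R/P fold ratio; mild -3R/-2P motif
# mimicking the family's conserved N-terminal determinants
plus1_preference_matrix <- function(rp_fold) {
  w <- matrix(1, 9L, 20L, dimnames = list(pspl_positions, aa_alphabet))
  w["-3", "R"] <- 6
  w["-2", "P"] <- 6
  w["+1", "R"] <- sqrt(rp_fold)
  w["+1", "P"] <- 1 / sqrt(rp_fold)
  w
}

#' Generate the packaged fixture study
#'
#' A desk-scale analog of an ancestral-kinase resurrection study: an
#' eight-taxon tree with three measured clades whose planted +1 preference
#' is P (root/CDK-like side), dual PR (LF4-like) and R (Ime2-like), and
#' whose DFGx character is L except in the Ime2-like clade (S), so the
#' trajectory P -> PR -> R and a single DFGx L->S transition are the ground
#' truth. Sequences (with implanted DFG/APE motifs), PSPL arrays, velocity
#' replicates and Michaelis-Menten datasets are all generated with recorded
#' parameters.
#'
#' @param seed integer seed driving every stochastic component.
#' @param dir optional directory; when given, writes `tree.nwk`,
#'   `alignment.fasta`, `pspl.csv`, `kinetics.csv`, `velocities.csv` and
#'   `manifest.json` there.
#' @param n_sites background alignment length.
#' @return list with `tree`, `alignment`, `sim` (the `sim_evolution`),
#'   `pspl` (named list of replicate lists, one per measured kinase),
#'   `velocities` (named list with `R`/`P` replicate triples), `kinetics`
#'   (named list of `R`/`P` data.frames), `measured_nodes`, `truth`
#'   (planted states, DFGx characters and transition), `seed`, and `dir`.
#' @export
generate_fixture_study <- function(seed = 1L, dir = NULL, n_sites = 120L) {
  seed <- as.integer(seed)
  nwk <- paste0("((cdk1:0.12,cdk2:0.12)AncP:0.15,((lf4a:0.10,lf4b:0.10)",
                "AncPR:0.10,(ime2a:0.08,ime2b:0.08)AncR:0.12)AncMid:0.08)",
                "AncRoot;")
  tree <- ape::read.tree(text = nwk)
  model <- subst_model("LG", alpha = 1, k = 4)
  sim <- simulate_evolution(tree, model, n_sites, indel_rate = 0.05,
                            seed = seed)

  # implant DFG..APE motifs: DFG at 50-52, DFGx at 53, APE at 74-76
  # (APE 21 residues downstream of DFG, inside the activation-loop window)
  ime2_clade <- c("ime2a", "ime2b", "AncR")
  nn <- n_tips(tree) + tree$Nnode
  chars <- do.call(rbind, strsplit(sim$truth$node_sequences, ""))
  motif_cols <- c(50:53, 74:76)
  for (i in seq_len(nn)) {
    lab <- node_label(tree, i)
    dfgx <- if (lab %in% ime2_clade) "S" else "L"
    chars[i, motif_cols] <- c("D", "F", "G", dfgx, "A", "P", "E")
    # remove spurious DFG triples elsewhere so the motif is unambiguous
    s <- paste(chars[i, ], collapse = "")
    hits <- gregexpr("DFG", s, fixed = TRUE)[[1]]
    for (h in hits) if (h != -1L && h != 50L) chars[i, h] <- "E"
  }
  sim$truth$node_sequences <- stats::setNames(
    apply(chars, 1, paste, collapse = ""),
    names(sim$truth$node_sequences))
  aln <- do.call(rbind, strsplit(sim$truth$node_sequences[tree$tip.label], ""))
  rownames(aln) <- tree$tip.label
  sim$alignment <- aln

  # planted +1 fold preferences (R/P): P-state 1/4, dual 1, R-state 4
  folds <- c(AncRoot = 1 / 4, cdk1 = 1 / 4, AncPR = 1, lf4a = 1,
             AncR = 4, ime2a = 4)
  pspl <- lapply(seq_along(folds), function(i) {
    simulate_pspl(plus1_preference_matrix(folds[i]), n_replicates = 2L,
                  noise_cv = 0.1, seed = seed + 100L + i,
                  kinase = names(folds)[i])
  })
  names(pspl) <- names(folds)

  # velocity triples with the same planted ratios (CV 10%)
  velocities <- lapply(seq_along(folds), function(i) {
    set.seed(seed + 200L + i)
    base <- 2
    sdlog <- sqrt(log(1 + 0.1^2))
    noise <- function(n) stats::rlnorm(n, -sdlog^2 / 2, sdlog)
    list(R = base * sqrt(folds[i]) * noise(3),
         P = base / sqrt(folds[i]) * noise(3))
  })
  names(velocities) <- names(folds)

  # Michaelis-Menten datasets for the three ancestral states
  concs <- c(0.25, 0.5, 1, 2, 5, 10, 25, 50)
  kin_par <- list(
    AncRoot = list(R = c(40, 3),    P = c(2.5, 10)),
    AncPR   = list(R = c(2, 8),     P = c(2, 8)),
    AncR    = list(R = c(2.2, 10.8), P = c(44.5, 3.3)))
  kinetics <- lapply(seq_along(kin_par), function(i) {
    lapply(stats::setNames(names(kin_par[[i]]), names(kin_par[[i]])),
           function(p1) {
      par <- kin_par[[i]][[p1]]
      simulate_kinetics(par[1], par[2], enzyme_nM = 10, concs = concs,
                        noise_cv = 0.05, n_replicates = 1L,
                        seed = seed + 300L + 10L * i +
                          as.integer(p1 == "P"))
    })
  })
  names(kinetics) <- names(kin_par)

  truth <- list(
    states = c(AncRoot = "P_pref", AncPR = "dual_PR", AncR = "R_pref"),
    plus1_fold = folds,
    dfgx = stats::setNames(
      ifelse(vapply(seq_len(nn), function(i) node_label(tree, i), "")
             %in% ime2_clade, "S", "L"),
      vapply(seq_len(nn), function(i) node_label(tree, i), "")),
    dfgx_transition = data.frame(parent = "AncMid", child = "AncR",
                                 from_residue = "L", to_residue = "S"))

  bundle <- list(tree = tree, alignment = aln, sim = sim, model = model,
                 pspl = pspl, velocities = velocities, kinetics = kinetics,
                 measured_nodes = names(folds), truth = truth, seed = seed,
                 dir = dir)
  if (!is.null(dir)) write_fixture_study(bundle, dir)
  bundle
}

# write the fixture bundle as plain-text files the CLI can consume
write_fixture_study <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ape::write.tree(bundle$tree, file.path(dir, "tree.nwk"))
  write_alignment(bundle$alignment, file.path(dir, "alignment.fasta"))
  pspl <- do.call(rbind, lapply(bundle$pspl, function(reps)
    do.call(rbind, reps)))
  utils::write.csv(pspl, file.path(dir, "pspl.csv"), row.names = FALSE)
  kin <- do.call(rbind, lapply(names(bundle$kinetics), function(nm) {
    do.call(rbind, lapply(names(bundle$kinetics[[nm]]), function(p1) {
      d <- bundle$kinetics[[nm]][[p1]]
      data.frame(peptide = paste0(nm, "_", p1), kinase = nm,
                 acceptor = "S", plus1 = p1, d)
    }))
  }))
  utils::write.csv(kin, file.path(dir, "kinetics.csv"), row.names = FALSE)
  vel <- do.call(rbind, lapply(names(bundle$velocities), function(nm) {
    v <- bundle$velocities[[nm]]
    rbind(data.frame(kinase = nm, plus1 = "R", replicate = 1:3, v0 = v$R),
          data.frame(kinase = nm, plus1 = "P", replicate = 1:3, v0 = v$P))
  }))
  utils::write.csv(vel, file.path(dir, "velocities.csv"), row.names = FALSE)
  manifest <- list(seed = bundle$seed,
                   measured_nodes = bundle$measured_nodes,
                   truth = list(states = as.list(bundle$truth$states),
                                plus1_fold = as.list(bundle$truth$plus1_fold),
                                dfgx_transition = bundle$truth$dfgx_transition))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
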