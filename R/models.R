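#' Build a reversible amino-acid rate matrix
#'
#' Assembles the instantaneous rate matrix \eqn{Q} of a general
#' time-reversible amino-acid substitution model from a symmetric
#' exchangeability matrix \eqn{S} and equilibrium frequencies \eqn{\pi}:
#' \eqn{Q_{ij} = s_{ij}\pi_j} for \eqn{i \ne j}, diagonal set so rows sum to
#' zero, and the whole matrix rescaled so the expected substitution rate at
#' equilibrium, \eqn{-\sum_i \pi_i Q_{ii}}, equals one. Branch lengths are
#' then in expected substitutions per site.
#'
#' The returned object caches the symmetric eigendecomposition of
#' \eqn{\Pi^{1/2} Q \Pi^{-1/2}} (real spectrum for reversible models), used
#' by [transition_matrix()].
#'
#' @param exchangeabilities symmetric non-negative 20x20 matrix (diagonal
#'   ignored), rows/columns in [aa_alphabet] order.
#' @param frequencies 20 strictly positive equilibrium frequencies summing to
#'   1 (renormalized if within 1e-6).
#' @param name optional model label.
#' @return An object of class `aa_rate_matrix`: list with elements
#'   `exchangeabilities`, `frequencies`, `Q`, `eigen` (values/vectors of the
#'   symmetrized matrix plus the similarity scalings), `name`.
#' @export
build_rate_matrix <- function(exchangeabilities, frequencies, name = "custom") {
  S <- as.matrix(exchangeabilities)
  if (!all(dim(S) == c(20L, 20L)))
    stop("exchangeabilities must be a 20x20 matrix", call. = FALSE)
  diag(S) <- 0
  if (any(S < 0)) stop("exchangeabilities must be non-negative", call. = FALSE)
  if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S))))
    stop("exchangeabilities must be symmetric", call. = FALSE)
  S <- (S + t(S)) / 2

  pi <- as.numeric(frequencies)
  if (length(pi) != 20L) stop("frequencies must have length 20", call. = FALSE)
  if (any(pi <= 0)) {
    stop("zero or negative frequency for residue(s): ",
         paste(aa_alphabet[pi <= 0], collapse = ", "), call. = FALSE)
  }
  if (abs(sum(pi) - 1) > 1e-6)
    stop("frequencies must sum to 1 (got ", format(sum(pi)), ")", call. = FALSE)
  pi <- pi / sum(pi)

  Q <- S * rep(pi, each = 20L)       # Q_ij = s_ij * pi_j
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))           # mean rate at equilibrium
  if (mu <= 0) stop("degenerate rate matrix: zero mean rate", call. = FALSE)
  Q <- Q / mu

  # symmetrized form has a real spectrum; exp(Qt) recovered by similarity
  sp <- sqrt(pi)
  B <- Q * (sp / rep(sp, each = 20L))          # diag(sp) Q diag(1/sp), B_ij = sp_i Q_ij / sp_j
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)

  structure(list(
    name = name,
    exchangeabilities = S,
    frequencies = stats::setNames(pi, aa_alphabet),
    Q = structure(Q, dimnames = list(aa_alphabet, aa_alphabet)),
    eigen = list(values = eig$values,
                 vectors = eig$vectors,
                 inv_scale = 1 / sp,   # left similarity:  diag(1/sp) V
                 scale = sp)           # right similarity: t(V) diag(sp)
  ), class = "aa_rate_matrix")
}

#' @export
print.aa_rate_matrix <- function(x, ...) {
  cat("Reversible amino-acid rate matrix:", x$name, "\n")
  cat("  mean rate at equilibrium: ",
      format(-sum(x$frequencies * diag(x$Q))), "\n")
  cat("  frequency range: ", format(min(x$frequencies)), "-",
      format(max(x$frequencies)), "\n")
  invisible(x)
}

#' Read an empirical replacement-matrix file
#'
#' Parses the standard plain-text layout used for empirical amino-acid
#' models: 19 lines giving the lower triangle of the symmetric
#' exchangeability matrix (row \eqn{i} holds columns \eqn{1..i-1}), followed
#' by 20 equilibrium frequencies, residues in [aa_alphabet] order. Lines
#' starting with `#` are comments.
#'
#' @param path file path.
#' @param name model label (defaults to the file stem).
#' @return An `aa_rate_matrix` (see [build_rate_matrix()]).
#' @export
read_paml_matrix <- function(path, name = NULL) {
  if (is.null(name))
    name <- toupper(sub("\\.[^.]*$", "", basename(path)))
  ln <- readLines(path, warn = FALSE)
  ln <- ln[!grepl("^\\s*#", ln)]
  vals <- as.numeric(unlist(strsplit(trimws(paste(ln, collapse = " ")), "\\s+")))
  vals <- vals[!is.na(vals)]
  if (length(vals) != 190L + 20L)
    stop("expected 190 exchangeabilities + 20 frequencies, got ",
         length(vals), " numbers in ", path, call. = FALSE)
  S <- matrix(0, 20L, 20L)
  k <- 0L
  for (i in 2:20) {                  # row-wise lower triangle
    S[i, 1:(i - 1L)] <- vals[k + seq_len(i - 1L)]
    k <- k + i - 1L
  }
  S <- S + t(S)
  build_rate_matrix(S, vals[191:210], name = name)
}

#' Load a bundled empirical substitution matrix
#'
#' @param name one of `"LG"`, `"WAG"`, `"JTT"`.
#' @return An `aa_rate_matrix`.
#' @export
empirical_matrix <- function(name = c("LG", "WAG", "JTT")) {
  name <- match.arg(toupper(name), c("LG", "WAG", "JTT"))
  path <- system.file("extdata", "models", paste0(tolower(name), ".dat"),
                      package = "kinasr", mustWork = TRUE)
  read_paml_matrix(path, name = name)
}

#' Discrete-gamma rate categories
#'
#' Discretizes the unit-mean gamma distribution (shape and rate both
#' \eqn{\alpha}) into `k` equal-probability categories, each represented by
#' its conditional mean. Category means follow from the incomplete-gamma
#' identity \eqn{E[X; X \in (a,b)] = F_{\alpha+1}(b) - F_{\alpha+1}(a)}
#' scaled by `k`, so the discrete distribution has mean exactly one.
#'
#' @param alpha gamma shape (> 0); small values mean strong among-site rate
#'   heterogeneity.
#' @param k number of categories (>= 1).
#' @return Object of class `gamma_rates`: list with `alpha`, `k`, `rates`
#'   (non-decreasing, mean 1) and `weights` (each 1/k).
#' @export
discretize_gamma <- function(alpha, k = 4L) {
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer", call. = FALSE)
  if (k == 1L) {
    rates <- 1
  } else {
    q <- stats::qgamma(seq(0, 1, length.out = k + 1L), shape = alpha, rate = alpha)
    # mass of gamma(alpha+1, alpha) between the quantile boundaries
    cdf1 <- stats::pgamma(q, shape = alpha + 1, rate = alpha)
    rates <- k * diff(cdf1)
    rates <- rates / (sum(rates) / k)  # guard roundoff; keeps mean exactly 1
  }
  structure(list(alpha = alpha, k = k, rates = rates,
                 weights = rep(1 / k, k)),
            class = "gamma_rates")
}

#' @export
print.gamma_rates <- function(x, ...) {
  cat("Discrete-gamma rates: alpha =", format(x$alpha), ", k =", x$k, "\n")
  cat("  rates:", paste(format(x$rates, digits = 4), collapse = " "), "\n")
  invisible(x)
}

#' Substitution model (matrix + among-site rate variation)
#'
#' Couples an empirical (or custom) rate matrix with an optional
#' discrete-gamma description of among-site rate variation. `free_params`
#' counts the model's estimated parameters for information criteria: 0 for a
#' fixed empirical matrix, +1 when the gamma shape is estimated.
#'
#' @param matrix an `aa_rate_matrix`, or a model name accepted by
#'   [empirical_matrix()].
#' @param gamma a `gamma_rates` object, or `NULL` for a single unit rate.
#' @param alpha,k shortcut: if `gamma` is missing and `alpha` given, calls
#'   [discretize_gamma()].
#' @param alpha_free logical; whether alpha is counted as an estimated
#'   parameter (default `TRUE` when gamma is present).
#' @return Object of class `subst_model`.
#' @export
subst_model <- function(matrix = "LG", gamma = NULL, alpha = NULL, k = 4L,
                        alpha_free = !is.null(gamma) || !is.null(alpha)) {
  if (is.character(matrix)) matrix <- empirical_matrix(matrix)
  stopifnot(inherits(matrix, "aa_rate_matrix"))
  if (is.null(gamma) && !is.null(alpha)) gamma <- discretize_gamma(alpha, k)
  if (!is.null(gamma)) stopifnot(inherits(gamma, "gamma_rates"))
  name <- matrix$name
  if (!is.null(gamma)) name <- paste0(name, "+G", gamma$k)
  structure(list(name = name, matrix = matrix, gamma = gamma,
                 free_params = if (!is.null(gamma) && alpha_free) 1L else 0L),
            class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  cat("Substitution model:", x$name, "\n")
  if (!is.null(x$gamma))
    cat("  gamma alpha =", format(x$gamma$alpha), "with", x$gamma$k,
        "categories\n")
  cat("  free parameters (beyond branch lengths):", x$free_params, "\n")
  invisible(x)
}

# rate categories of a model as a plain vector (1 when no gamma)
model_rates <- function(model) {
  if (is.null(model$gamma)) 1 else model$gamma$rates
}

#' Transition probability matrix
#'
#' \eqn{P(t) = \exp(Q t r)} for branch length `t` (substitutions/site) and
#' rate multiplier `rate`, via the cached symmetric eigendecomposition of the
#' rate matrix.
#'
#' @param model a `subst_model` or `aa_rate_matrix`.
#' @param t branch length, >= 0.
#' @param rate positive rate multiplier (e.g. a gamma category rate).
#' @return 20x20 row-stochastic matrix in [aa_alphabet] order.
#' @export
transition_matrix <- function(model, t, rate = 1) {
  rm <- if (inherits(model, "subst_model")) model$matrix else model
  stopifnot(inherits(rm, "aa_rate_matrix"))
  if (!is.finite(t) || t < 0) stop("branch length t must be >= 0", call. = FALSE)
  if (!is.finite(rate) || rate <= 0) stop("rate must be > 0", call. = FALSE)
  e <- rm$eigen
  ex <- exp(e$values * t * rate)
  P <- (e$inv_scale * e$vectors) %*% (ex * t(e$vectors * e$scale))
  # clip tiny negative roundoff and renormalize rows
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(aa_alphabet, aa_alphabet)
  P
}
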