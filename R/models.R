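# Amino-acid alphabet in PAML order; all model matrices follow it.
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Residues whose enrichment tracks warm adaptation (IVYWREL-style proxy) and
# residues depleted in thermophile proteomes; used by the composition coupling.
AA_THERMO_UP   <- c("I", "V", "Y", "W", "R", "E", "L")
AA_THERMO_DOWN <- c("D", "N", "Q", "T", "S", "H", "A")

#' Thermo-indicator vector over the 20 amino acids
#'
#' +1 for residues enriched in warm-adapted proteins (I, V, Y, W, R, E, L),
#' -1 for residues depleted (D, N, Q, T, S, H, A), 0 otherwise.
#'
#' @return Named numeric vector of length 20.
#' @export
thermo_indicator <- function() {
  d <- stats::setNames(numeric(20), AA20)
  d[AA_THERMO_UP] <- 1
  d[AA_THERMO_DOWN] <- -1
  d
}

#' Discrete-gamma category rates
#'
#' Yang-style discretisation: `k` equal-probability categories, each
#' represented by its conditional mean, rescaled to mean exactly 1.
#'
#' @param shape Positive gamma shape parameter.
#' @param k Number of categories.
#' @return Numeric vector of `k` relative rates with mean 1.
#' @export
discrete_gamma_rates <- function(shape, k = 4L) {
  stopifnot(is.numeric(shape), shape > 0, k >= 1)
  if (k == 1L) return(1)
  # category boundaries at equal quantiles; category mean via the
  # incomplete-gamma identity E[X; a<X<b] = shape/rate * (F_{shape+1}(b)-F_{shape+1}(a))
  q <- stats::qgamma(seq(0, 1, length.out = k + 1), shape = shape, rate = shape)
  p_hi <- stats::pgamma(q, shape = shape + 1, rate = shape)
  r <- k * diff(p_hi)
  r / mean(r)
}

#' Construct an amino-acid substitution model
#'
#' Builds a reversible 20-state model from either uniform (Poisson)
#' exchangeabilities or an empirical table (LG, WAG, ...) taken from
#' phangorn's model set. The rate matrix is normalised to one expected
#' substitution per site at its equilibrium frequencies. Gamma rate
#' heterogeneity uses `k` equal-probability discrete categories.
#'
#' @param name Model id: `"poisson"` or any amino-acid model phangorn ships
#'   (e.g. `"LG"`, `"WAG"`, `"JTT"`); case-insensitive for `"poisson"`.
#' @param shape Gamma shape; `NULL` or `Inf` means rate homogeneity.
#' @param k Number of discrete gamma categories (default 4).
#' @param freqs Optional equilibrium frequencies overriding the model's own
#'   (length 20, order `AA20`); renormalised to sum to 1.
#' @return Object of class `subst_model`: exchangeabilities `S`, frequencies
#'   `pi`, normalised generator `Q`, eigendecomposition for fast transition
#'   probabilities, gamma `shape`, category count `k` and rates `rates`.
#' @export
subst_model <- function(name = "poisson", shape = NULL, k = 4L, freqs = NULL) {
  nm <- as.character(name)
  if (tolower(nm) == "poisson") {
    S <- matrix(1, 20, 20)
    diag(S) <- 0
    pi0 <- rep(1 / 20, 20)
  } else {
    am <- get(".aamodels", envir = asNamespace("phangorn"))
    hit <- am[match(tolower(nm), tolower(am))]
    if (is.na(hit)) {
      stop("unknown substitution model '", nm, "'; available: poisson, ",
           paste(am, collapse = ", "), call. = FALSE)
    }
    tab <- get(paste0(".", hit), envir = asNamespace("phangorn"))
    S <- matrix(0, 20, 20)
    S[lower.tri(S)] <- tab$Q
    S <- S + t(S)
    pi0 <- as.numeric(tab$bf)
    nm <- hit
  }
  if (!is.null(freqs)) {
    stopifnot(length(freqs) == 20, all(freqs >= 0), sum(freqs) > 0)
    pi0 <- as.numeric(freqs) / sum(freqs)
  }
  names(pi0) <- AA20
  dimnames(S) <- list(AA20, AA20)
  shape <- if (is.null(shape) || !is.finite(shape)) NULL else as.numeric(shape)
  rates <- if (is.null(shape)) 1 else discrete_gamma_rates(shape, k)
  k_eff <- length(rates)
  m <- structure(
    list(name = nm, S = S, pi = pi0, shape = shape, k = k_eff, rates = rates),
    class = "subst_model")
  m$Q <- build_generator(S, pi0)
  m$eig <- reversible_eigen(m$Q, pi0)
  m
}

# Q_ij = S_ij * pi_j, diagonal so rows sum to 0, scaled to 1 expected
# substitution per site: -sum_i pi_i Q_ii = 1.
build_generator <- function(S, pi) {
  Q <- S * rep(pi, each = 20)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  if (mu <= 0) stop("degenerate rate matrix (zero total rate)", call. = FALSE)
  Q / mu
}

# Eigendecomposition of a reversible generator via symmetrisation:
# B = D^{1/2} Q D^{-1/2} is symmetric; P(t) = U exp(L t) Uinv.
reversible_eigen <- function(Q, pi) {
  d <- sqrt(pi)
  B <- Q * (d %o% (1 / d))
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  U <- e$vectors / d
  Uinv <- t(e$vectors) * rep(d, each = 20)
  list(values = e$values, U = U, Uinv = Uinv)
}

#' Transition probability matrix P(t)
#'
#' @param model A `subst_model` (or a list with an `eig` component).
#' @param t Branch length in expected substitutions per site (>= 0).
#' @return 20 x 20 stochastic matrix.
#' @export
transition_prob <- function(model, t) {
  stopifnot(t >= 0)
  e <- model$eig
  P <- e$U %*% (exp(e$values * t) * e$Uinv)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Temperature-shifted equilibrium frequencies
#'
#' Tilts baseline frequencies in logit space along the thermo-indicator
#' direction: log pi_i(T) = log pi0_i + beta * (T - 37) * d_i - log Z.
#'
#' @param pi0 Baseline frequencies (length 20, order `AA20`).
#' @param topt Temperature in degrees C.
#' @param beta Coupling strength per degree C (0 decouples composition).
#' @param ref Reference temperature (default 37).
#' @return Frequencies summing to 1.
#' @export
thermal_freqs <- function(pi0, topt, beta, ref = 37) {
  d <- thermo_indicator()
  w <- log(pmax(pi0, 1e-12)) + beta * (topt - ref) * d
  w <- exp(w - max(w))
  stats::setNames(w / sum(w), AA20)
}
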