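#' Load a named amino-acid exchangeability matrix
#'
#' The package ships the published LG, WAG and JTT matrices as plain-text
#' files (residue order, 190 upper-triangle exchangeabilities, 20 stationary
#' frequencies).
#'
#' @param name one of `"LG"`, `"WAG"`, `"JTT"`, or a path to a file in the
#'   same format.
#' @return list with `S` (20x20 symmetric exchangeabilities, zero diagonal)
#'   and `freqs` (length-20, sums to 1), both in [AA_ALPHABET] order.
#' @export
load_exchangeability <- function(name = "LG") {
  path <- if (file.exists(name)) name else
    system.file("extdata", "models", paste0(name, ".dat"), package = "placeprof")
  if (!nzchar(path) || !file.exists(path)) {
    stop("unknown substitution matrix: ", name)
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  order_in <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  ex <- as.numeric(strsplit(trimws(lines[[2]]), "\\s+")[[1]])
  fr <- as.numeric(strsplit(trimws(lines[[3]]), "\\s+")[[1]])
  stopifnot(length(ex) == 190L, length(fr) == 20L)
  S <- matrix(0, 20, 20, dimnames = list(order_in, order_in))
  k <- 1L
  for (i in 1:19) for (j in (i + 1):20) { S[i, j] <- S[j, i] <- ex[k]; k <- k + 1L }
  names(fr) <- order_in
  # reorder to the package's canonical residue order
  S <- S[AA_ALPHABET, AA_ALPHABET]
  fr <- fr[AA_ALPHABET]
  fr <- fr / sum(fr)
  list(S = S, freqs = unname(fr))
}

#' Discrete-gamma rate categories
#'
#' Mean-of-quantile-interval discretization of a gamma(shape, rate = shape)
#' distribution (mean 1) into `k` equal-probability categories. Category `i`'s
#' rate is the conditional mean of the distribution over the quantile interval
#' `((i-1)/k, i/k)`, so the category rates average exactly to 1.
#'
#' @param alpha gamma shape parameter (> 0).
#' @param k number of categories (>= 1).
#' @return numeric vector of `k` increasing rates with mean 1.
#' @export
discrete_gamma_rates <- function(alpha, k) {
  stopifnot(alpha > 0, k >= 1)
  if (k == 1L) return(1)
  q <- stats::qgamma(seq(0, 1, length.out = k + 1), shape = alpha, rate = alpha)
  # E[X; X in (a,b)] for gamma(a,rate=a) = P(b; a+1) - P(a; a+1) (mean 1)
  cum <- stats::pgamma(q, shape = alpha + 1, rate = alpha)
  k * diff(cum)
}

#' Build an amino-acid substitution model
#'
#' Constructs the reversible rate matrix `Q[i,j] = S[i,j] * pi[j]`, rescaled
#' to one expected substitution per unit branch length, with discrete-gamma
#' rate heterogeneity. The symmetric eigendecomposition is cached so that
#' transition matrices `P(t) = exp(Qt)` are cheap.
#'
#' @param matrix matrix name or path accepted by [load_exchangeability()].
#' @param shape gamma shape alpha (> 0); default 1.
#' @param k number of gamma categories; default 4.
#' @param freqs `"model"` (matrix-supplied, default), `"empirical"` is handled
#'   by callers that have an alignment, or a numeric length-20 vector.
#' @return object of class `aa_model` with elements `Q`, `freqs`, `rates`,
#'   `shape`, `k`, `name` and cached eigen-vectors.
#' @export
build_model <- function(matrix = "LG", shape = 1, k = 4, freqs = "model") {
  ex <- load_exchangeability(matrix)
  pf <- if (is.numeric(freqs)) {
    stopifnot(length(freqs) == 20L, all(freqs > 0))
    freqs / sum(freqs)
  } else ex$freqs
  Q <- ex$S * rep(pf, each = 20)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pf * diag(Q))
  Q <- Q / mu
  sp <- sqrt(pf)
  B <- Q * (sp %o% (1 / sp))       # diag(sp) Q diag(1/sp), symmetric
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  left <- eig$vectors / sp          # diag(1/sp) %*% V
  right <- t(eig$vectors * sp)      # t(V) %*% diag(sp)
  structure(list(
    name = if (is.character(matrix)) matrix else "custom",
    Q = Q, freqs = pf, shape = shape, k = as.integer(k),
    rates = discrete_gamma_rates(shape, k),
    eval = eig$values, left = left, right = right
  ), class = "aa_model")
}

#' Transition probability matrix P(t) for one rate category
#'
#' @param model an `aa_model`.
#' @param t branch length (>= 0), in expected substitutions per site at rate 1.
#' @param category rate category index in `1..k` (default 1); the effective
#'   time is `t * rates[category]`.
#' @return 20x20 stochastic matrix, rows indexed by ancestral state.
#' @export
substitution_probability <- function(model, t, category = 1L) {
  if (t < 0) stop("negative branch length")
  r <- model$rates[[category]]
  P <- model$left %*% (exp(model$eval * t * r) * model$right)
  # eigendecomposition can leave tiny negative entries; clamp for safety
  P[P < 0] <- 0
  P
}
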