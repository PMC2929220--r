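# Amino-acid substitution models. Empirical exchangeabilities and equilibrium
# frequencies for JTT and Dayhoff are taken from phangorn's model data; the
# Poisson model is the uniform 20-state rate matrix. Every Q is rescaled to
# one expected substitution per site at equilibrium.

#' Amino-acid substitution model
#'
#' Builds a time-reversible instantaneous rate matrix `Q` scaled to one
#' expected substitution per site, with its equilibrium frequencies `pi` and a
#' precomputed spectral decomposition for fast transition matrices.
#'
#' * `"poisson"`: all exchanges equally likely, uniform frequencies;
#' * `"dayhoff"`, `"jtt"`: empirical exchangeabilities and frequencies
#'   (via phangorn's model tables).
#'
#' @param name One of `"poisson"`, `"dayhoff"`, `"jtt"`.
#' @return An object of class `substitution_model` with fields `name`, `Q`
#'   (20 x 20, rows sum to zero), `pi`, and eigen-decomposition components.
#' @export
substitution_model <- function(name = c("jtt", "dayhoff", "poisson")) {
  name <- match.arg(name)
  if (name == "poisson") {
    S <- matrix(1, 20, 20)
    diag(S) <- 0
    pi <- rep(1 / 20, 20)
  } else {
    key <- c(jtt = ".JTT", dayhoff = ".Dayhoff")[[name]]
    mod <- get(key, envir = asNamespace("phangorn"))
    S <- matrix(0, 20, 20)
    S[lower.tri(S)] <- mod$Q
    S <- S + t(S)
    pi <- unname(mod$bf)
    # phangorn stores models in the same ARNDCQEGHILKMFPSTWYV residue order
    stopifnot(identical(toupper(names(mod$bf)), AA20))
  }
  pi <- pi / sum(pi)
  Q <- S %*% diag(pi)
  diag(Q) <- -rowSums(Q)
  rate <- -sum(pi * diag(Q))
  Q <- Q / rate
  dimnames(Q) <- list(AA20, AA20)
  # reversible Q: diag(sqrt(pi)) Q diag(1/sqrt(pi)) is symmetric
  sp <- sqrt(pi)
  A <- diag(sp) %*% Q %*% diag(1 / sp)
  eig <- eigen((A + t(A)) / 2, symmetric = TRUE)
  structure(list(name = name, Q = Q, pi = setNames(pi, AA20),
                 eig_values = eig$values,
                 eig_left = diag(1 / sp) %*% eig$vectors,
                 eig_right = t(eig$vectors) %*% diag(sp)),
            class = "substitution_model")
}

#' @export
print.substitution_model <- function(x, ...) {
  cat("<substitution_model>", x$name,
      "(20x20 rate matrix, 1 expected substitution/site)\n")
  invisible(x)
}

#' Transition probability matrix exp(Q d)
#'
#' @param model A [substitution_model()].
#' @param d Branch length in expected substitutions per site (`d >= 0`).
#' @return 20 x 20 stochastic matrix `P` with `P[x, y] = P(y at time d | x)`.
#' @export
transition_matrix <- function(model, d) {
  stopifnot(inherits(model, "substitution_model"), d >= 0, is.finite(d))
  P <- model$eig_left %*% (exp(model$eig_values * d) * model$eig_right)
  P[P < 0] <- 0  # clip eigen round-off
  P <- P / rowSums(P)
  dimnames(P) <- list(AA20, AA20)
  P
}
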