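#' Fit the admixture model by EM
#'
#' Maximum-likelihood estimation of the K-cluster admixture model: each
#' individual i has ancestry fractions `q_i` (summing to 1) and each
#' cluster c cluster-specific allele frequencies `p_c`, and the dosage
#' `x_ik ~ Binomial(2, sum_c q_ic p_ck)`. The binomial log-likelihood is
#' maximised by EM from random Dirichlet(1) Q / uniform P starts; the best
#' of `n_restarts` runs by log-likelihood is returned. The log-likelihood
#' is checked to be non-decreasing at every iteration. Frequencies are
#' clamped to `[1e-6, 1 - 1e-6]` so the likelihood stays finite. Missing
#' genotypes are simply dropped from the sums.
#'
#' @param x A [geno_data] object (post-QC, LD-pruned data recommended).
#' @param K Number of ancestral clusters (`K = 1` is the closed form:
#'   `Q = 1`, `P` = sample allele frequencies).
#' @param seed Integer seed (restarts draw their starts from it).
#' @param max_iter,tol EM stopping rule: stop when the log-likelihood
#'   gain drops below `tol` or after `max_iter` iterations.
#' @param n_restarts Independent random starts.
#' @return Object of class `snppop_admixture`: `Q` tibble (`sample_id`,
#'   `population`, `Q1..QK`), `P` (K x SNPs matrix), `loglik`, `K`,
#'   `iterations`, `converged`, `loglik_history`.
#' @export
admixture_em <- function(x, K, seed = 1L, max_iter = 2000L, tol = 1e-6,
                         n_restarts = 5L) {
  stopifnot(K >= 1L)
  g <- x$genotypes
  storage.mode(g) <- "double"

  best <- NULL
  withr::with_seed(seed, {
    for (rs in seq_len(max(1L, n_restarts))) {
      fit <- admixture_em_once(g, K, max_iter = max_iter, tol = tol)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
  })

  q_tbl <- tibble::as_tibble(stats::setNames(
    as.data.frame(best$Q), paste0("Q", seq_len(K))))
  q_tbl <- dplyr::bind_cols(x$samples, q_tbl)
  colnames(best$P) <- x$map$snp_id

  structure(
    list(Q = q_tbl, P = best$P, loglik = best$loglik, K = K,
         iterations = best$iterations, converged = best$converged,
         loglik_history = best$history),
    class = "snppop_admixture"
  )
}

admixture_em_once <- function(g, K, max_iter, tol) {
  n <- nrow(g); m <- ncol(g)
  obs <- !is.na(g)
  x1 <- g; x1[!obs] <- 0           # dosage, 0 where missing
  x0 <- (2 - g); x0[!obs] <- 0     # 2 - dosage
  m_i <- rowSums(obs)              # non-missing SNPs per sample
  lchoose_const <- sum(lchoose(2, g[obs]))
  eps <- 1e-6

  if (K == 1L) {
    p <- colSums(x1) / pmax(colSums(obs) * 2, 1)
    p <- pmin(pmax(p, eps), 1 - eps)
    F1 <- matrix(p, n, m, byrow = TRUE)
    ll <- lchoose_const +
      sum((x1 * log(F1) + x0 * log(1 - F1))[obs])
    return(list(Q = matrix(1, n, 1), P = matrix(p, 1, m), loglik = ll,
                iterations = 0L, converged = TRUE, history = ll))
  }

  Q <- matrix(stats::rgamma(n * K, 1), n, K)
  Q <- Q / rowSums(Q)
  P <- matrix(stats::runif(K * m, 0.05, 0.95), K, m)

  ll_old <- -Inf
  history <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    F1 <- Q %*% P
    F1 <- pmin(pmax(F1, eps), 1 - eps)
    T1 <- x1 / F1          # zero where missing
    T0 <- x0 / (1 - F1)

    ll <- lchoose_const + sum((x1 * log(F1) + x0 * log(1 - F1))[obs])
    if (ll < ll_old - 1e-6 * (abs(ll_old) + 1)) {
      stop("admixture EM log-likelihood decreased; this is a bug",
           call. = FALSE)
    }
    history <- c(history, ll)
    if (is.finite(ll_old) && ll - ll_old < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll

    Qn <- matrix(0, n, K)
    Pn <- matrix(0, K, m)
    for (cc in seq_len(K)) {
      a_row <- T1 %*% (P[cc, ])            # n-vector: sum_k T1 p_ck
      b_row <- T0 %*% (1 - P[cc, ])
      Qn[, cc] <- Q[, cc] * (a_row + b_row)
      a_col <- crossprod(T1, Q[, cc])      # m-vector: sum_i T1 q_ic
      b_col <- crossprod(T0, Q[, cc])
      num <- P[cc, ] * a_col
      den <- num + (1 - P[cc, ]) * b_col
      Pn[cc, ] <- ifelse(den > 0, num / den, P[cc, ])
    }
    Q <- Qn / pmax(rowSums(Qn), .Machine$double.xmin)
    P <- pmin(pmax(Pn, eps), 1 - eps)
  }
  list(Q = Q, P = P, loglik = ll_old, iterations = it,
       converged = converged, history = history)
}

#' @export
print.snppop_admixture <- function(x, ...) {
  cat(sprintf(
    "<snppop_admixture> K = %d; log-likelihood = %.2f (%d iterations%s)\n",
    x$K, x$loglik, x$iterations,
    if (x$converged) "" else ", not converged"))
  invisible(x)
}

#' Choose K by cross-validated prediction error
#'
#' Cell-holdout cross-validation of the admixture model: the non-missing
#' genotype cells are split into `folds` random folds; for each fold the
#' model is fitted with that fold masked and scored by the mean binomial
#' deviance of the masked cells under the fitted `Q %*% P` dosage
#' frequencies. Folds that would mask an entire sample or SNP are redrawn.
#' The optimal K is the error minimiser.
#'
#' @param x A [geno_data] object.
#' @param K_values Integer vector of K values to score.
#' @param folds Number of folds.
#' @param seed Integer seed; the same seed reproduces the same folds and
#'   fits exactly.
#' @param n_restarts,max_iter,tol Passed to the per-fold EM fits.
#' @return Tibble: `K`, `cv_error` (mean held-out deviance per masked
#'   cell), with the chosen K in `attr(, "best_K")`.
#' @export
admixture_cv <- function(x, K_values, folds = 5L, seed = 1L,
                         n_restarts = 2L, max_iter = 500L, tol = 1e-4) {
  stopifnot(length(K_values) >= 1L)
  g <- x$genotypes
  obs_idx <- which(!is.na(g))
  n <- nrow(g); m <- ncol(g)

  fold_of <- withr::with_seed(seed, {
    repeat {
      f <- sample(rep_len(seq_len(folds), length(obs_idx)))
      ok <- TRUE
      for (k in seq_len(folds)) {
        masked <- obs_idx[f == k]
        keep <- matrix(TRUE, n, m)
        keep[masked] <- FALSE
        keep[-obs_idx] <- FALSE
        if (any(rowSums(keep) == 0L) || any(colSums(keep) == 0L)) {
          ok <- FALSE
          break
        }
      }
      if (ok) break
    }
    f
  })

  errors <- matrix(NA_real_, length(K_values), folds)
  for (ki in seq_along(K_values)) {
    K <- K_values[ki]
    for (fd in seq_len(folds)) {
      masked <- obs_idx[fold_of == fd]
      g_train <- g
      g_train[masked] <- NA_integer_
      x_train <- x
      x_train$genotypes <- g_train
      fit <- admixture_em(x_train, K, seed = seed + 1000L * fd + K,
                          max_iter = max_iter, tol = tol,
                          n_restarts = n_restarts)
      Qm <- as.matrix(fit$Q[, paste0("Q", seq_len(K)), drop = FALSE])
      F1 <- Qm %*% fit$P
      F1 <- pmin(pmax(F1, 1e-6), 1 - 1e-6)
      xh <- g[masked]
      fh <- F1[masked]
      dev <- -2 * mean(lchoose(2, xh) + xh * log(fh) +
                         (2 - xh) * log(1 - fh))
      errors[ki, fd] <- dev
    }
  }
  out <- tibble::tibble(K = as.integer(K_values),
                        cv_error = rowMeans(errors))
  attr(out, "best_K") <- out$K[which.min(out$cv_error)]
  out
}
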