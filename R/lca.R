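#' Default binning rules for latent class analysis
#'
#' Thresholds for turning continuous locus features into categorical
#' indicators. All numeric bins are half-open on the right (`[a, b)`), so a
#' phastCons score of exactly 0.2 falls in the middle bin and a length of
#' exactly 20 residues in the medium bin.
#'
#' @param phastcons_breaks Conservation bins (default 0, 0.2, 0.8, 1).
#' @param length_breaks Length bins in residues (default 0, 20, 50, Inf).
#' @param tpm_cut Transcription cut on maximum per-sample TPM (default 0.1).
#' @param tau_cut Specificity cut on tau (default 0.8).
#' @return List of class `lca_binning_rules`.
#' @export
lca_binning_rules <- function(phastcons_breaks = c(0, 0.2, 0.8, 1),
                              length_breaks = c(0, 20, 50, Inf),
                              tpm_cut = 0.1, tau_cut = 0.8) {
  out <- list(phastcons_breaks = phastcons_breaks,
              length_breaks = length_breaks,
              tpm_cut = tpm_cut, tau_cut = tau_cut)
  class(out) <- "lca_binning_rules"
  out
}

.cut_right_open <- function(x, breaks, labels) {
  idx <- findInterval(x, breaks, rightmost.closed = TRUE)
  if (any(idx < 1 | idx > length(labels), na.rm = TRUE)) {
    stop("value out of declared range")
  }
  factor(labels[idx], levels = labels)
}

#' Bin raw locus features into categorical indicators
#'
#' Recognized numeric columns: `phastcons` (three conservation bins),
#' `length_aa` (short / medium / long), `max_tpm` (transcribed above the TPM
#' cut or not), `tau_tissue` and `tau_dev` (specific above the tau cut or
#' not). Any other column is passed through as a factor. Rows with missing
#' values in any indicator are flagged for exclusion (they cannot enter the
#' latent class fit).
#'
#' @param features Data frame of raw per-locus features.
#' @param rules Binning rules from [lca_binning_rules()].
#' @return Data frame of factors with attribute `complete` (logical vector:
#'   row has no missing indicator).
#' @export
bin_features <- function(features, rules = lca_binning_rules()) {
  stopifnot(inherits(rules, "lca_binning_rules"))
  out <- list()
  for (nm in names(features)) {
    x <- features[[nm]]
    out[[nm]] <- switch(nm,
      phastcons = {
        if (any(x < 0 | x > 1, na.rm = TRUE)) stop("phastcons out of [0,1]")
        .cut_right_open(x, rules$phastcons_breaks,
                        c("nonconserved", "ambiguous", "conserved"))
      },
      length_aa = {
        if (any(x < 0, na.rm = TRUE)) stop("negative length")
        .cut_right_open(x, rules$length_breaks, c("short", "medium", "long"))
      },
      max_tpm = {
        if (any(x < 0, na.rm = TRUE)) stop("negative TPM")
        factor(ifelse(x > rules$tpm_cut, "transcribed", "untranscribed"),
               levels = c("untranscribed", "transcribed"))
      },
      tau_tissue = ,
      tau_dev = {
        if (any(x < 0 | x > 1, na.rm = TRUE)) stop("tau out of [0,1]")
        factor(ifelse(x > rules$tau_cut, "specific", "broad"),
               levels = c("broad", "specific"))
      },
      factor(x))
  }
  res <- as.data.frame(out, stringsAsFactors = TRUE)
  attr(res, "complete") <- stats::complete.cases(res)
  res
}

# Convert a factor table to an integer matrix plus level metadata.
.lca_encode <- function(table) {
  stopifnot(is.data.frame(table), nrow(table) > 0L)
  if (any(!stats::complete.cases(table))) {
    stop("table has missing values; exclude incomplete rows before fitting")
  }
  x <- vapply(table, function(col) as.integer(as.factor(col)),
              integer(nrow(table)))
  if (is.null(dim(x))) x <- matrix(x, nrow = nrow(table))
  levels <- lapply(table, function(col) levels(as.factor(col)))
  list(x = x, levels = levels, n_levels = vapply(levels, length, integer(1)))
}

# One EM run from a random start; returns pi, rho, logL, iterations.
.lca_em_once <- function(x, n_levels, K, tol, max_iter) {
  n <- nrow(x)
  J <- ncol(x)
  pi <- rep(1 / K, K)
  rho <- lapply(n_levels, function(L) {
    m <- matrix(stats::rexp(K * L), K, L)
    m / rowSums(m)
  })
  ll_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    lp <- matrix(log(pi), n, K, byrow = TRUE)
    for (j in seq_len(J)) {
      lr <- log(pmax(rho[[j]], 1e-300))
      lp <- lp + t(lr)[x[, j], , drop = FALSE]
    }
    mx <- apply(lp, 1, max)
    w <- exp(lp - mx)
    rs <- rowSums(w)
    ll <- sum(mx + log(rs))
    post <- w / rs
    pi <- colMeans(post)
    for (j in seq_len(J)) {
      L <- n_levels[j]
      num <- vapply(seq_len(L), function(l) colSums(post[x[, j] == l, ,
                                                         drop = FALSE]),
                    numeric(K))
      if (is.null(dim(num))) num <- matrix(num, nrow = K)
      denom <- colSums(post)
      rho[[j]] <- pmax(num / denom, 1e-12)
      rho[[j]] <- rho[[j]] / rowSums(rho[[j]])
    }
    if (ll - ll_old < tol && iter > 1L) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  list(pi = pi, rho = rho, logL = ll_old, converged = converged)
}

#' Fit a latent class model by EM with random restarts
#'
#' Fits a finite mixture of independent categorical distributions ("latent
#' class model", no covariates) by expectation-maximization from
#' `n_restarts` random initializations, keeping the best log-likelihood.
#' Restarts that reach the top log-likelihood with materially different
#' parameters indicate under-identification and are counted in
#' `n_distinct_optima`. Classes are relabeled in order of decreasing mixing
#' proportion for reporting stability.
#'
#' @param table Data frame of factors with no missing values.
#' @param K Number of classes (>= 1).
#' @param n_restarts Number of random restarts (default 100).
#' @param tol Absolute log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter Maximum EM iterations per restart (default 5000).
#' @param seed Optional integer seed.
#' @return Object of class `lca_model`: `K`, `pi`, `rho` (list of K x L
#'   conditional probability matrices per indicator), `logL`, `n_params`,
#'   `AIC`, `BIC`, `converged`, `n_distinct_optima`, `levels`, `n`,
#'   `restart_logL`.
#' @export
fit_lca <- function(table, K, n_restarts = 100L, tol = 1e-8,
                    max_iter = 5000L, seed = NULL) {
  stopifnot(K >= 1L)
  enc <- .lca_encode(table)
  n <- nrow(enc$x)
  n_patterns <- nrow(unique(as.data.frame(enc$x)))
  if (K > n_patterns) {
    stop("K = ", K, " exceeds the ", n_patterns, " distinct response patterns")
  }
  if (!is.null(seed)) set.seed(seed)
  runs <- lapply(seq_len(n_restarts), function(r) {
    .lca_em_once(enc$x, enc$n_levels, K, tol, max_iter)
  })
  lls <- vapply(runs, `[[`, numeric(1), "logL")
  best <- runs[[which.max(lls)]]
  # count materially distinct optima among restarts tying at the top
  top <- which(lls >= max(lls) - 1e-6)
  fingerprints <- lapply(runs[top], function(r) {
    ord <- order(r$pi, decreasing = TRUE)
    c(r$pi[ord], unlist(lapply(r$rho, function(m) m[ord, , drop = FALSE])))
  })
  distinct <- 1L
  if (length(fingerprints) > 1L) {
    base <- fingerprints[[1]]
    distinct <- 1L + sum(vapply(fingerprints[-1], function(f) {
      max(abs(f - base)) > 1e-3
    }, logical(1)))
  }
  ord <- order(best$pi, decreasing = TRUE)
  pi <- best$pi[ord]
  rho <- lapply(seq_along(best$rho), function(j) {
    m <- best$rho[[j]][ord, , drop = FALSE]
    dimnames(m) <- list(paste0("class", seq_len(K)), enc$levels[[j]])
    m
  })
  names(rho) <- names(table)
  n_params <- (K - 1L) + K * sum(enc$n_levels - 1L)
  out <- list(K = K, pi = pi, rho = rho, logL = best$logL,
              n_params = n_params,
              AIC = -2 * best$logL + 2 * n_params,
              BIC = -2 * best$logL + n_params * log(n),
              converged = best$converged,
              n_distinct_optima = distinct,
              levels = enc$levels, n = n, restart_logL = lls)
  class(out) <- "lca_model"
  out
}

#' @export
print.lca_model <- function(x, ...) {
  cat(sprintf(
    "Latent class model: K = %d, n = %d, logL = %.3f\n  AIC = %.2f, BIC = %.2f, pi = %s%s\n",
    x$K, x$n, x$logL, x$AIC, x$BIC,
    paste(sprintf("%.3f", x$pi), collapse = ", "),
    if (x$n_distinct_optima > 1L) "  [multiple tied optima]" else ""))
  invisible(x)
}

#' Information criteria of a fitted latent class model
#'
#' `AIC = -2 logL + 2 p` and `BIC = -2 logL + p log(n)` with
#' `p = (K - 1) + K * sum(L_j - 1)` free parameters.
#'
#' @param model An `lca_model`.
#' @param n Sample size (default: the size the model was fitted on).
#' @return List with `AIC`, `BIC`, `n_params`.
#' @export
information_criteria <- function(model, n = model$n) {
  stopifnot(inherits(model, "lca_model"))
  p <- model$n_params
  list(AIC = -2 * model$logL + 2 * p,
       BIC = -2 * model$logL + p * log(n),
       n_params = p)
}

#' Select the number of latent classes
#'
#' Chooses the smallest-BIC model among candidates that converged to a
#' unique top optimum. Models whose restarts tied at the top with distinct
#' parameters are excluded as under-identified. The report notes whether AIC
#' agrees with the BIC choice.
#'
#' @param models List of `lca_model` objects fitted on the same table.
#' @return List with `K` (chosen), `by_bic`, `by_aic`, `agreement`
#'   (logical), `excluded` (K values dropped as under-identified), and a
#'   summary `table`.
#' @export
select_classes <- function(models) {
  stopifnot(length(models) >= 1L,
            all(vapply(models, inherits, logical(1), "lca_model")))
  tab <- data.frame(
    K = vapply(models, `[[`, numeric(1), "K"),
    logL = vapply(models, `[[`, numeric(1), "logL"),
    AIC = vapply(models, `[[`, numeric(1), "AIC"),
    BIC = vapply(models, `[[`, numeric(1), "BIC"),
    converged = vapply(models, `[[`, logical(1), "converged"),
    n_distinct_optima = vapply(models, `[[`, numeric(1), "n_distinct_optima"))
  eligible <- tab$converged & tab$n_distinct_optima == 1L
  if (!any(eligible)) stop("no converged, identified model")
  excluded <- tab$K[!eligible]
  el <- tab[eligible, ]
  by_bic <- el$K[which.min(el$BIC)]
  by_aic <- el$K[which.min(el$AIC)]
  list(K = by_bic, by_bic = by_bic, by_aic = by_aic,
       agreement = by_bic == by_aic, excluded = excluded, table = tab)
}

#' Posterior class membership and modal assignment
#'
#' Applies Bayes' rule row by row under the fitted model. Ties in the modal
#' class go to the lowest class index.
#'
#' @param model An `lca_model`.
#' @param table Data frame of factors whose levels are all known to the
#'   model.
#' @return List with `posterior` (n x K matrix, rows sum to 1) and
#'   `modal_class` (integer vector).
#' @export
posterior_assign <- function(model, table) {
  stopifnot(inherits(model, "lca_model"), ncol(table) == length(model$rho))
  n <- nrow(table)
  K <- model$K
  lp <- matrix(log(model$pi), n, K, byrow = TRUE)
  for (j in seq_len(ncol(table))) {
    lev <- colnames(model$rho[[j]])
    idx <- match(as.character(table[[j]]), lev)
    if (anyNA(idx)) {
      stop("unseen level in indicator '", names(table)[j], "'")
    }
    lp <- lp + t(log(pmax(model$rho[[j]], 1e-300)))[idx, , drop = FALSE]
  }
  mx <- apply(lp, 1, max)
  w <- exp(lp - mx)
  post <- w / rowSums(w)
  modal <- apply(post, 1, which.max)   # which.max takes the first (lowest) tie
  list(posterior = post, modal_class = as.integer(modal))
}
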