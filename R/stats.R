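# Two-group Mann-Whitney U comparison, implemented from first principles.
# U is reported as min(U1, U2), the convention under which U tends to 0 as
# the two groups' rank distributions separate.

#' Mann-Whitney U test for two independent samples
#'
#' Ranks both samples jointly with mid-ranks for ties and computes
#' `U1 = R1 - n1(n1+1)/2`, `U = min(U1, U2)`. The default
#' `"asymptotic_cc"` method uses the tie-corrected normal approximation with
#' continuity correction,
#' `z = (U - n1 n2 / 2 + 0.5) / sigma` with
#' `sigma = sqrt(n1 n2 / 12 * ((N^3 - N) - sum(t^3 - t)) / (N (N - 1)))`
#' over tie-group sizes `t`, and a two-sided p-value `2 * Phi(z)` capped at
#' 1. The `"exact"` method enumerates all `choose(N, n1)` group labelings
#' (no ties allowed) and returns `2 * P(U' <= U)` capped at 1. When every
#' observation is tied, `sigma = 0` and p is 1.
#'
#' @param a,b Numeric samples (each non-empty).
#' @param method `"asymptotic_cc"` (default) or `"exact"`.
#' @return Object of class `mann_whitney`: list with `U`, `U1`, `U2`, `p`,
#'   `n1`, `n2`, `method` and (asymptotic method only) `z`.
#' @export
mann_whitney <- function(a, b, method = c("asymptotic_cc", "exact")) {
  method <- match.arg(method)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) stop("both samples must be non-empty")
  if (anyNA(a) || anyNA(b)) stop("samples must not contain NA")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  U2 <- n1 * n2 - U1
  U <- min(U1, U2)
  z <- NA_real_
  if (method == "asymptotic_cc") {
    t <- table(c(a, b))
    tie_term <- sum(t^3 - t)
    sigma2 <- n1 * n2 / 12 * ((N^3 - N) - tie_term) / (N * (N - 1))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - n1 * n2 / 2 + 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(z))
    }
  } else {
    if (anyDuplicated(c(a, b))) {
      stop("exact method requires samples without ties")
    }
    splits <- utils::combn(N, n1)
    u_all <- colSums(matrix(r[splits], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- min(1, 2 * mean(u_all <= U))
  }
  structure(list(U = U, U1 = U1, U2 = U2, p = p, n1 = n1, n2 = n2,
                 method = method, z = z),
            class = "mann_whitney")
}

#' @export
print.mann_whitney <- function(x, ...) {
  cat(sprintf("Mann-Whitney U test (%s): U = %g, p = %.4g (n1 = %d, n2 = %d)\n",
              x$method, x$U, x$p, x$n1, x$n2))
  invisible(x)
}

#' Rested-to-exercised fold ratio of group means
#'
#' @param rested_mean,exercised_mean Group means; the exercised mean must be
#'   positive (a zero denominator is reported as `Inf` with a warning, i.e.
#'   flagged unbounded).
#' @return `rested_mean / exercised_mean`.
#' @export
fold_ratio <- function(rested_mean, exercised_mean) {
  if (any(exercised_mean < 0) || any(rested_mean < 0)) {
    stop("group means must be non-negative")
  }
  if (any(exercised_mean == 0)) {
    warning("exercised mean is zero; fold ratio is unbounded")
  }
  rested_mean / exercised_mean
}

#' Mann-Whitney comparisons of all indices by site and selection
#'
#' Runs [mann_whitney()] (exercised vs rested) for every index at every site
#' and selection present in a table of section-level indices, mirroring the
#' layout of site-by-index comparison tables.
#'
#' @param sections Data frame of [section_morphometry()] rows for both
#'   groups.
#' @param indices Index columns to compare.
#' @param method Passed to [mann_whitney()].
#' @return Data frame with `site`, `selection`, `index`, `U`, `p`, `n1`
#'   (exercised), `n2` (rested).
#' @export
compare_groups <- function(sections,
                           indices = c("Ct_Ar_mm2", "N_Ca", "Tt_Ca_Ar_mm2",
                                       "N_Ca_per_Ct_Ar",
                                       "Tt_Ca_Ar_per_Ct_Ar"),
                           method = "asymptotic_cc") {
  cells <- unique(sections[, c("site", "selection")])
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    sel <- sections$site == cells$site[i] &
      sections$selection == cells$selection[i]
    ex <- sections[sel & sections$group == "exercised", , drop = FALSE]
    re <- sections[sel & sections$group == "rested", , drop = FALSE]
    if (nrow(ex) == 0L || nrow(re) == 0L) {
      stop("site ", cells$site[i], ": both groups need at least one section")
    }
    for (ix in indices) {
      mw <- mann_whitney(ex[[ix]], re[[ix]], method = method)
      rows[[length(rows) + 1L]] <- data.frame(
        site = cells$site[i], selection = cells$selection[i], index = ix,
        U = mw$U, p = mw$p, n1 = mw$n1, n2 = mw$n2,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
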