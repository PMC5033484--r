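#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Classical univariate repeated-measures ANOVA for a fully crossed
#' within-subject design with one observation per subject x cell. For every
#' main effect and interaction the F ratio is computed from the orthonormal
#' contrast projection of the subject-by-cell matrix: with `M` the Kronecker
#' product of orthonormal between-level contrasts (effect factors) and
#' normalized unit vectors (averaged-over factors), `Z = Y M`,
#' `SS_effect = n * sum(colMeans(Z)^2)` and `SS_error = sum((Z - colMeans)^2)`,
#' giving `F = (SS_effect/df1) / (SS_error/df2)` with `df1 = q`,
#' `df2 = q (n-1)`. The Greenhouse-Geisser epsilon is
#' `tr(S)^2 / (q * sum(S^2))` with `S` the covariance of `Z`, exactly 1 for
#' two-level effects; corrected p-values use epsilon-scaled degrees of
#' freedom. Partial eta squared is `SS_effect / (SS_effect + SS_error)`,
#' identically `F df1 / (F df1 + df2)`.
#'
#' @param data long-format data frame; duplicated subject x cell rows are
#'   averaged (with a message).
#' @param dv name of the dependent-variable column.
#' @param subject name of the subject identifier column.
#' @param within character vector of within-subject factor column names.
#' @return tibble with one row per effect: `effect`, `df_num`, `df_den`, `F`,
#'   `gg_epsilon`, `p_uncorrected`, `p_gg`, `partial_eta_sq`.
#' @export
rm_anova <- function(data, dv, subject = "subject", within) {
  stopifnot(length(within) >= 1, dv %in% names(data), subject %in% names(data),
            all(within %in% names(data)))
  data <- as.data.frame(data)
  for (f in within) data[[f]] <- factor(data[[f]])
  data[[subject]] <- factor(data[[subject]])
  levs <- lapply(data[within], levels)
  nlev <- vapply(levs, length, integer(1))
  subjects <- levels(data[[subject]])
  n <- length(subjects)
  if (n < 2) stop("at least two subjects required")

  # subject x cell matrix, cells in expand.grid order (first factor fastest)
  grid <- do.call(expand.grid, c(levs, list(stringsAsFactors = FALSE)))
  cell_key <- do.call(paste, c(grid, list(sep = "\x1f")))
  row_key <- do.call(paste, c(lapply(data[within], as.character), list(sep = "\x1f")))
  idx <- match(row_key, cell_key)

  counts <- table(factor(data[[subject]], subjects),
                  factor(idx, seq_along(cell_key)))
  if (any(counts == 0)) {
    miss <- which(counts == 0, arr.ind = TRUE)
    labs <- apply(miss, 1, function(r) {
      paste0(subjects[r[1]], ": ", gsub("\x1f", "/", cell_key[r[2]]))
    })
    stop(sprintf("incomplete cells (subject: cell): %s",
                 paste(utils::head(labs, 10), collapse = "; ")))
  }
  if (any(counts > 1)) message("averaging duplicated subject x cell observations")
  sums <- tapply(data[[dv]], list(factor(data[[subject]], subjects),
                                  factor(idx, seq_along(cell_key))), mean)
  Y <- matrix(sums, nrow = n, dimnames = NULL)

  # orthonormal contrast (levels x levels-1) orthogonal to the unit vector
  ortho_contrasts <- function(k) {
    if (k == 1) return(matrix(numeric(0), 1, 0))
    H <- stats::contr.helmert(k)
    H %*% diag(1 / sqrt(colSums(H^2)), ncol(H))
  }

  out <- list()
  n_fac <- length(within)
  for (mask in seq_len(2^n_fac - 1)) {
    in_eff <- as.logical(bitwAnd(mask, 2^(seq_len(n_fac) - 1)))
    mats <- lapply(seq_len(n_fac), function(j) {
      if (in_eff[j]) ortho_contrasts(nlev[j])
      else matrix(1 / sqrt(nlev[j]), nlev[j], 1)
    })
    # expand.grid order: factor 1 fastest -> kronecker with last factor leftmost
    M <- Reduce(kronecker, rev(mats))
    q <- ncol(M)
    if (q == 0) next
    Z <- Y %*% M
    zbar <- colMeans(Z)
    ss_eff <- n * sum(zbar^2)
    Zc <- sweep(Z, 2, zbar)
    ss_err <- sum(Zc^2)
    df1 <- q
    df2 <- q * (n - 1)
    # degenerate case: dv constant across conditions (both SS vanish) -> F = 0
    tol <- 1e-12 * (sum(Y^2) + .Machine$double.xmin)
    if (ss_eff < tol && ss_err < tol) { ss_eff <- 0; ss_err <- 1 }
    Fval <- (ss_eff / df1) / (ss_err / df2)
    if (q == 1) {
      eps <- 1
    } else {
      S <- stats::cov(Z)
      eps <- sum(diag(S))^2 / (q * sum(S^2))
    }
    out[[length(out) + 1]] <- tibble::tibble(
      effect = paste(within[in_eff], collapse = ":"),
      df_num = df1, df_den = df2, F = Fval, gg_epsilon = eps,
      p_uncorrected = stats::pf(Fval, df1, df2, lower.tail = FALSE),
      p_gg = stats::pf(Fval, df1 * eps, df2 * eps, lower.tail = FALSE),
      partial_eta_sq = ss_eff / (ss_eff + ss_err)
    )
  }
  dplyr::bind_rows(out)
}

#' Repeated-measures ANOVA on a filtered subset (planned comparison)
#'
#' Subsets the measurement table by the given label values, then runs
#' [rm_anova()] on the remaining factors — e.g. the deviant effect within
#' butterflies only.
#'
#' @param data long-format data.
#' @param filter named list of column = value restrictions.
#' @param dv,subject,within as in [rm_anova()].
#' @return ANOVA tibble, see [rm_anova()].
#' @export
planned_contrast <- function(data, filter, dv, subject = "subject", within) {
  sel <- rep(TRUE, nrow(data))
  for (f in names(filter)) sel <- sel & data[[f]] == filter[[f]]
  sub <- data[sel, , drop = FALSE]
  if (nrow(sub) == 0) stop("planned contrast subset is empty")
  rm_anova(sub, dv = dv, subject = subject, within = within)
}

#' Holm-corrected paired t-tests between factor levels
#'
#' Post-hoc pairwise comparisons on subject-level cell means.
#'
#' @param data long-format data (one value per subject x level after
#'   averaging over other factors).
#' @param dv dependent-variable column.
#' @param factor_name column whose levels are compared.
#' @param subject subject column.
#' @return tibble `level_a`, `level_b`, `t`, `df`, `p`, `p_holm`.
#' @export
posthoc_pairwise <- function(data, dv, factor_name, subject = "subject") {
  agg <- stats::aggregate(data[[dv]],
                          list(subject = data[[subject]], level = data[[factor_name]]),
                          mean)
  levs <- sort(unique(as.character(agg$level)))
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  rows <- lapply(pairs, function(p) {
    a <- agg$x[agg$level == p[1]][order(agg$subject[agg$level == p[1]])]
    b <- agg$x[agg$level == p[2]][order(agg$subject[agg$level == p[2]])]
    tt <- stats::t.test(a, b, paired = TRUE)
    tibble::tibble(level_a = p[1], level_b = p[2],
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p = tt$p.value)
  })
  out <- dplyr::bind_rows(rows)
  out$p_holm <- stats::p.adjust(out$p, "holm")
  out
}
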