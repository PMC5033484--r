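# Independent oracles and small fixtures shared across the test files.
# These deliberately use different algorithms from the package code paths.

# tiny montage: n channels on a circle (plus optional EOG) -------------------
tiny_montage <- function(n = 8, eog = FALSE) {
  ang <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  mon <- tibble::tibble(name = paste0("ch", seq_len(n)),
                        x = cos(ang), y = sin(ang), z = 0.2, eog = FALSE)
  if (eog) mon <- rbind(mon, tibble::tibble(name = "VEOG", x = 0, y = 0.95,
                                            z = -0.2, eog = TRUE))
  class(mon) <- c("erp_montage", class(mon))
  mon
}

# random zero-mean map over given channels
random_map <- function(ch, sd = 1) {
  v <- stats::rnorm(length(ch), 0, sd)
  v <- v - mean(v)
  names(v) <- ch
  v
}

# brute-force repeated-measures ANOVA via inclusion-exclusion over
# uncorrected sums of squares (classical marginal-means route) ---------------
#   U(S) = sum over cells of S of (cell total)^2 / (obs per cell)
#   SS of interaction E = sum_{S subset E} (-1)^{|E|-|S|} U(S)
oracle_rm_anova <- function(data, dv, subject, within) {
  data <- as.data.frame(data)
  facs <- c(within, subject)
  for (f in facs) data[[f]] <- factor(data[[f]])
  N <- nrow(data)
  y <- data[[dv]]
  U <- function(S) {
    if (length(S) == 0) return(sum(y)^2 / N)
    key <- interaction(data[S], drop = FALSE)
    tot <- tapply(y, key, sum)
    cnt <- tapply(y, key, length)
    sum(tot^2 / cnt)
  }
  ss_interaction <- function(E) {
    s <- 0
    for (m in 0:(2^length(E) - 1)) {
      S <- E[as.logical(bitwAnd(m, 2^(seq_along(E) - 1)))]
      s <- s + (-1)^(length(E) - length(S)) * U(S)
    }
    s
  }
  nlev <- vapply(data[facs], nlevels, integer(1))
  names(nlev) <- facs
  n_subj <- nlev[[subject]]
  out <- list()
  for (m in seq_len(2^length(within) - 1)) {
    E <- within[as.logical(bitwAnd(m, 2^(seq_along(within) - 1)))]
    ss_eff <- ss_interaction(E)
    ss_err <- ss_interaction(c(E, subject))
    df1 <- prod(nlev[E] - 1)
    df2 <- df1 * (n_subj - 1)
    out[[length(out) + 1]] <- data.frame(
      effect = paste(E, collapse = ":"),
      df_num = df1, df_den = df2,
      F = (ss_eff / df1) / (ss_err / df2),
      partial_eta_sq = ss_eff / (ss_eff + ss_err),
      gg_epsilon = oracle_gg_epsilon(data, dv, subject, within, E),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Greenhouse-Geisser epsilon via orthonormal *polynomial* contrasts (a
# different basis from the implementation; epsilon is basis-invariant)
oracle_gg_epsilon <- function(data, dv, subject, within, E) {
  levs <- lapply(data[within], levels)
  grid <- do.call(expand.grid, c(levs, list(stringsAsFactors = FALSE)))
  key_all <- do.call(paste, c(lapply(data[within], as.character), list(sep = ".")))
  key_grid <- do.call(paste, c(grid, list(sep = ".")))
  subj <- factor(data[[subject]])
  Y <- matrix(NA_real_, nlevels(subj), nrow(grid))
  for (i in seq_len(nrow(data))) {
    Y[as.integer(subj[i]), match(key_all[i], key_grid)] <- data[[dv]][i]
  }
  mats <- lapply(within, function(f) {
    k <- length(levs[[f]])
    if (f %in% E) {
      P <- stats::contr.poly(k)
      P %*% diag(1 / sqrt(colSums(P^2)), ncol(P))
    } else matrix(1 / sqrt(k), k, 1)
  })
  M <- Reduce(kronecker, rev(mats))
  q <- ncol(M)
  if (q == 1) return(1)
  S <- stats::cov(Y %*% M)
  sum(diag(S))^2 / (q * sum(S^2))
}

# exhaustive TANOVA oracle: loop every relabeling, plain diss ----------------
oracle_tanova_p <- function(A, B) {
  n <- dim(A)[1]; TT <- dim(A)[3]
  diss <- function(u, v) {
    sqrt(mean((u / sqrt(mean(u^2)) - v / sqrt(mean(v^2)))^2))
  }
  p <- numeric(TT)
  for (t in seq_len(TT)) {
    obs <- diss(colMeans(A[, , t]), colMeans(B[, , t]))
    cnt <- 0L; total <- 0L
    for (m in 0:(2^n - 1)) {
      swap <- as.logical(bitwAnd(m, 2^(seq_len(n) - 1)))
      a <- A[, , t]; b <- B[, , t]
      a[swap, ] <- B[swap, , t]; b[swap, ] <- A[swap, , t]
      if (diss(colMeans(a), colMeans(b)) >= obs - 1e-12) cnt <- cnt + 1L
      total <- total + 1L
    }
    p[t] <- cnt / total
  }
  p
}

# direct per-timepoint back-fit explained-variance oracle --------------------
oracle_backfit_ev <- function(templates, X, polarity = TRUE) {
  C <- ncol(X)
  g <- sqrt(rowMeans(X^2))
  tot <- sum(g^2)
  K <- nrow(templates)
  ev <- numeric(K)
  for (t in seq_len(nrow(X))) {
    if (g[t] < 1e-300) next
    cors <- vapply(seq_len(K), function(k) {
      sum(X[t, ] * templates[k, ]) /
        sqrt(sum(X[t, ]^2) * sum(templates[k, ]^2))
    }, numeric(1))
    pick <- if (polarity) which.max(cors) else which.max(abs(cors))
    cc <- if (polarity) cors[pick] else abs(cors[pick])
    ev[pick] <- ev[pick] + (g[t] * cc)^2
  }
  ev / tot
}

# all valid role sequences for a tiny oddball block (brute force) ------------
oracle_valid_sequences <- function(n_std, n_dev, run_lengths) {
  n <- n_std + n_dev
  pos <- utils::combn(n, n_dev, simplify = FALSE)
  ok <- Filter(function(p) {
    gaps <- diff(c(0, p)) - 1
    all(gaps %in% run_lengths)
  }, pos)
  vapply(ok, function(p) {
    s <- rep("S", n); s[p] <- "D"; paste(s, collapse = "")
  }, character(1))
}

# subset an epoch set by trial index
ep_subset <- function(ep, idx) {
  ep$data <- ep$data[, , idx, drop = FALSE]
  ep$trials <- ep$trials[idx, , drop = FALSE]
  ep
}

# evoked wrapper around a plain matrix
make_evoked <- function(data, times, montage, fs = 1000, ref = "average") {
  if (is.null(rownames(data)))
    rownames(data) <- scalp_channels(montage)[seq_len(nrow(data))]
  erp_evoked(data, times = times, sampling_rate = fs, montage = montage,
             reference = ref)
}
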