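#' Oddball design configuration
#'
#' Describes the stimulus stream of a four-block visual oddball experiment:
#' per block, frequent standards presented in short runs, interleaved with two
#' kinds of rare deviants (non-targets, differing from standards in colour
#' only, and targets, differing in both colour and category). Across blocks
#' every (category, colour) stimulus cell rotates through the standard,
#' non-target and target roles.
#'
#' @param n_blocks number of blocks.
#' @param n_standards_per_block standards per block.
#' @param n_nontarget_deviants,n_target_deviants deviants of each kind per block.
#' @param run_lengths admissible numbers of consecutive standards before each
#'   deviant (a subset of 3, 4, 5 in the default design).
#' @param stim_duration stimulus duration, ms.
#' @param iti_choices inter-trial intervals sampled uniformly per trial, ms.
#' @param categories,colours stimulus category and colour-plate labels.
#' @param n_exemplars greyscale base images per category.
#' @param role_rotation tibble with columns `block`, `role`, `category`,
#'   `colour` assigning each role's stimulus cell per block; `NULL` uses the
#'   default rotation in which every cell serves every role across the blocks.
#' @return a list of class `design_config`.
#' @export
design_config <- function(n_blocks = 4,
                          n_standards_per_block = 640,
                          n_nontarget_deviants = 80,
                          n_target_deviants = 80,
                          run_lengths = c(3L, 4L, 5L),
                          stim_duration = 400,
                          iti_choices = c(450, 500, 550),
                          categories = c("butterfly", "face"),
                          colours = c("blue", "green"),
                          n_exemplars = 80,
                          role_rotation = NULL) {
  stopifnot(n_blocks >= 1, n_standards_per_block >= 0,
            n_nontarget_deviants >= 0, n_target_deviants >= 0,
            all(run_lengths >= 1), stim_duration > 0, all(iti_choices >= 0))
  run_lengths <- sort(unique(as.integer(run_lengths)))
  if (is.null(role_rotation)) role_rotation <- default_role_rotation(categories, colours, n_blocks)
  cfg <- list(
    n_blocks = as.integer(n_blocks),
    n_standards_per_block = as.integer(n_standards_per_block),
    n_nontarget_deviants = as.integer(n_nontarget_deviants),
    n_target_deviants = as.integer(n_target_deviants),
    run_lengths = run_lengths,
    stim_duration = stim_duration,
    iti_choices = iti_choices,
    categories = categories,
    colours = colours,
    n_exemplars = as.integer(n_exemplars),
    role_rotation = role_rotation
  )
  class(cfg) <- "design_config"
  cfg
}

# Default four-block rotation: each (category, colour) cell is standard,
# non-target and target exactly once across blocks. Targets always oppose the
# standard in both category and colour; non-targets in colour only.
default_role_rotation <- function(categories, colours, n_blocks) {
  stopifnot(length(categories) == 2, length(colours) == 2, n_blocks == 4)
  cat1 <- categories[1]; cat2 <- categories[2]
  col1 <- colours[1]; col2 <- colours[2]
  tibble::tribble(
    ~block, ~role,        ~category, ~colour,
    1L, "standard",  cat1, col2,
    1L, "nontarget", cat1, col1,
    1L, "target",    cat2, col1,
    2L, "standard",  cat2, col1,
    2L, "nontarget", cat2, col2,
    2L, "target",    cat1, col2,
    3L, "standard",  cat1, col1,
    3L, "nontarget", cat1, col2,
    3L, "target",    cat2, col2,
    4L, "standard",  cat2, col2,
    4L, "nontarget", cat2, col1,
    4L, "target",    cat1, col1
  )
}

#' Enumerate the stimulus set implied by a design
#'
#' Each greyscale base image appears once under each colour plate, so the
#' default design (80 exemplars per category, 2 categories, 2 colours) yields
#' 320 distinct stimuli.
#'
#' @param design a `design_config`.
#' @return tibble with one row per stimulus: `stimulus_id`, `category`,
#'   `exemplar`, `colour`.
#' @export
enumerate_stimuli <- function(design) {
  g <- expand.grid(exemplar = seq_len(design$n_exemplars),
                   category = design$categories,
                   colour = design$colours,
                   stringsAsFactors = FALSE)
  g <- g[order(g$category, g$exemplar, g$colour), ]
  tibble::tibble(
    stimulus_id = sprintf("%s_%03d_%s", g$category, g$exemplar, g$colour),
    category = g$category, exemplar = g$exemplar, colour = g$colour
  )
}

# Find the most balanced multiset of run lengths: counts c_v >= 0 with
# sum(c) = n_runs and sum(c * v) = n_standards. Returns NULL when infeasible.
balanced_run_counts <- function(run_lengths, n_runs, n_standards) {
  v <- as.integer(run_lengths)
  best <- NULL; best_spread <- Inf
  recurse <- function(idx, counts, left_runs, left_std) {
    if (idx == length(v)) {
      if (left_std == left_runs * v[idx]) {
        counts[idx] <- left_runs
        spread <- max(counts) - min(counts)
        if (spread < best_spread) { best <<- counts; best_spread <<- spread }
      }
      return(invisible())
    }
    for (k in seq.int(0L, left_runs)) {
      rem_std <- left_std - k * v[idx]
      rem_runs <- left_runs - k
      # remaining values bound the achievable sum
      if (rem_std < rem_runs * min(v[(idx + 1):length(v)])) next
      if (rem_std > rem_runs * max(v[(idx + 1):length(v)])) next
      counts[idx] <- k
      recurse(idx + 1L, counts, rem_runs, rem_std)
    }
  }
  if (length(v) == 1) {
    if (n_standards == n_runs * v) return(stats::setNames(n_runs, v))
    return(NULL)
  }
  recurse(1L, integer(length(v)), as.integer(n_runs), as.integer(n_standards))
  if (is.null(best)) return(NULL)
  stats::setNames(best, v)
}

#' Generate one block's pseudo-random oddball trial sequence
#'
#' Standards are presented in runs whose lengths are drawn from
#' `design$run_lengths` (counts chosen as balanced as the totals permit), each
#' run followed by one deviant; non-target and target deviants are interleaved
#' in random order. Consequently no two deviants are ever adjacent. Targets
#' require the response button opposite to the one shared by standards and
#' non-targets.
#'
#' @param design a `design_config`.
#' @param block block index (selects the role rotation row).
#' @param seed integer seed; the sequence is deterministic given
#'   `(design, block, seed)`.
#' @return tibble with one row per trial: `block`, `trial`, `role`,
#'   `category`, `colour`, `onset_ms`, `required_response`.
#' @export
build_block_sequence <- function(design, block, seed) {
  stopifnot(inherits(design, "design_config"))
  if (missing(seed) || is.null(seed)) stop("a seed is required for reproducible sequences")
  n_dev <- design$n_nontarget_deviants + design$n_target_deviants
  if (n_dev < 1) stop("configuration error: at least one deviant is required")
  counts <- balanced_run_counts(design$run_lengths, n_dev, design$n_standards_per_block)
  if (is.null(counts)) {
    stop(sprintf(
      "configuration error: no multiset of %d run lengths from {%s} sums to %d standards",
      n_dev, paste(design$run_lengths, collapse = ","), design$n_standards_per_block))
  }
  roles_here <- design$role_rotation[design$role_rotation$block == block, ]
  if (nrow(roles_here) == 0) stop(sprintf("configuration error: no role rotation for block %d", block))
  cell <- function(role) roles_here[roles_here$role == role, c("category", "colour")]

  set.seed(as.integer(seed))
  resample <- function(x) x[sample.int(length(x))]   # safe for length-1 vectors
  runs <- resample(rep(as.integer(names(counts)), counts))
  dev_roles <- resample(rep(c("nontarget", "target"),
                            c(design$n_nontarget_deviants, design$n_target_deviants)))
  role_seq <- unlist(lapply(seq_along(runs), function(i) {
    c(rep("standard", runs[i]), dev_roles[i])
  }))
  n_trials <- length(role_seq)
  cells <- dplyr::bind_rows(lapply(role_seq, cell))
  iti <- sample(design$iti_choices, n_trials, replace = TRUE)
  onset <- 1000 + cumsum(c(0, (design$stim_duration + iti)[-n_trials]))
  target_button <- if (block %% 2 == 1) 5L else 1L
  other_button <- if (target_button == 5L) 1L else 5L
  tibble::tibble(
    block = as.integer(block),
    trial = seq_len(n_trials),
    role = role_seq,
    category = cells$category,
    colour = cells$colour,
    onset_ms = onset,
    required_response = ifelse(role_seq == "target", target_button, other_button)
  )
}

#' Generate trial sequences for all blocks of an experiment
#'
#' @param design a `design_config`.
#' @param seed integer base seed; per-block seeds are derived deterministically.
#' @return tibble of all blocks' trials (see [build_block_sequence()]).
#' @export
build_experiment_sequences <- function(design, seed) {
  set.seed(as.integer(seed))
  block_seeds <- sample.int(.Machine$integer.max - 1L, design$n_blocks)
  dplyr::bind_rows(lapply(seq_len(design$n_blocks), function(b) {
    build_block_sequence(design, b, block_seeds[b])
  }))
}
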