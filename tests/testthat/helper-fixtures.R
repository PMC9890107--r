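# In-code fixtures: small trial tables built from a compact session spec.
#
# sessions: list of lists with fields
#   participant, session, experimenter, lab (ids),
#   erotic  — logical vector of erotic-trial successes (in order),
#   nonerotic — count of interleaved non-erotic trials (successes alternate)
# Rows are laid out erotic-first per session, sessions concatenated in the
# order given; deposit_order is global row order.
make_fixture_table <- function(sessions) {
  rows <- list()
  for (s in sessions) {
    lab <- if (is.null(s$lab)) "lab1" else s$lab
    n_e <- length(s$erotic)
    n_ne <- if (is.null(s$nonerotic)) 0L else s$nonerotic
    success <- c(s$erotic, rep(c(TRUE, FALSE), length.out = n_ne))
    type <- c(rep("erotic", n_e), rep("nonerotic", n_ne))
    guess <- rep("left", n_e + n_ne)
    target <- ifelse(success, guess, "right")
    rows[[length(rows) + 1]] <- data.frame(
      session_id = s$session, participant_id = s$participant,
      lab_id = lab, experimenter_id = s$experimenter,
      trial_index = seq_len(n_e + n_ne), trial_type = type,
      guessed_side = guess, target_side = target, success = success,
      timestamp_hash = sprintf("%s-%02d", s$session, seq_len(n_e + n_ne)),
      stringsAsFactors = FALSE
    )
  }
  df <- do.call(rbind, rows)
  df$deposit_order <- seq_len(nrow(df)) - 1L
  trial_table(df, source = "fixture")
}

# Canonical three-session inclusion fixture: one complete 18-erotic
# session, one terminated after 7 erotic trials, one by a test-account
# experimenter. Confirmatory filter keeps 18 + 7 = 25 erotic trials.
three_session_fixture <- function() {
  make_fixture_table(list(
    list(participant = "pA", session = "s1", experimenter = "e1",
         erotic = rep(c(TRUE, FALSE), 9), nonerotic = 18L),
    list(participant = "pB", session = "s2", experimenter = "e1",
         erotic = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE), nonerotic = 7L),
    list(participant = "pC", session = "s3", experimenter = "tester",
         erotic = rep(TRUE, 18), nonerotic = 18L)
  ))
}

# trial table with one participant per element of `rates`, each completing
# 18 erotic trials with round(rate * 18) successes placed evenly
participants_fixture <- function(rates, trials = 18L) {
  sessions <- lapply(seq_along(rates), function(i) {
    k <- round(rates[[i]] * trials)
    succ <- rep(FALSE, trials)
    if (k > 0) succ[seq_len(k)] <- TRUE
    list(participant = sprintf("p%02d", i), session = sprintf("s%02d", i),
         experimenter = "e1", erotic = succ)
  })
  make_fixture_table(sessions)
}

# brute-force quadrature for the marginal likelihood of (k, n) under a
# truncated beta prior; independent oracle for bf01()
quadrature_m1 <- function(k, n, a, b) {
  norm <- stats::integrate(function(p) stats::dbeta(p, a, b), 0.5, 1,
                           rel.tol = 1e-12)$value
  # integrate only where the (likelihood x prior) product has mass, and
  # scale out its peak: p^k (1-p)^(n-k) underflows for n ~ 100 and its
  # peak is far narrower than (0.5, 1) for large n
  a_post <- k + a; b_post <- n - k + b
  center <- a_post / (a_post + b_post)
  sd_post <- sqrt(center * (1 - center) / (a_post + b_post))
  lo <- max(0.5, center - 50 * sd_post)
  hi <- min(1 - 1e-12, max(center + 50 * sd_post, 0.5 + 100 * sd_post))
  p_peak <- min(max(k / max(n, 1), lo), hi)
  log_scale <- k * log(p_peak) + (n - k) * log1p(-p_peak)
  val <- stats::integrate(function(p) {
    exp(k * log(p) + (n - k) * log1p(-p) - log_scale) * stats::dbeta(p, a, b) / norm
  }, lo, hi, rel.tol = 1e-12)$value
  list(value = val * exp(log_scale), log_value = log(val) + log_scale)
}

# brute-force earth mover's distance for equal-size multisets: minimum
# mean absolute displacement over all assignments
emd_bruteforce <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) <= 6)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  min(vapply(perms(y), function(p) mean(abs(x - p)), numeric(1)))
}

# grid-search shortest interval holding `level` mass of a Beta(a, b)
hdi_gridsearch <- function(a, b, level, grid_n = 20000L) {
  lo_grid <- seq(0, stats::qbeta(1 - level, a, b), length.out = grid_n)
  hi_grid <- stats::qbeta(stats::pbeta(lo_grid, a, b) + level, a, b)
  i <- which.min(hi_grid - lo_grid)
  c(lo_grid[i], hi_grid[i])
}

# small design configuration for fast sequential tests (two looks)
small_design <- function(points = c(360L, 720L)) {
  design_config(analysis_points = points)
}
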