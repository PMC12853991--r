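# small fixtures shared across test files; everything is generated in code

tiny_design <- function(n = 5) {
  tibble::tibble(
    cohort = rep(c("c1", "c2"), each = 2),
    group = rep(c("healthy", "MASLD"), 2),
    role = rep(c("control", "case"), 2),
    n = rep(n, 4)
  )
}

tiny_truth <- function(seed = 42L, n_families = 4, ...) {
  truth_config(
    n_families = n_families,
    S_range = c(2L, 4L),
    length_range = c(120L, 220L),
    cohort_design = tiny_design(),
    library_size_range = c(2e5, 4e5),
    seed = seed,
    ...
  )
}

# independent exact two-sided Mann-Whitney oracle: full enumeration of all
# group-A labelings, p = 2 * min(P(Ua <= ua), P(Ua >= ua)) capped at 1
enum_mw <- function(a, b) {
  x <- c(a, b)
  n_a <- length(a)
  r <- rank(x)
  u_a_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  combos <- utils::combn(length(x), n_a)
  u_all <- apply(combos, 2, function(idx) {
    sum(r[idx]) - n_a * (n_a + 1) / 2
  })
  p <- 2 * min(mean(u_all <= u_a_obs), mean(u_all >= u_a_obs))
  list(U = min(u_a_obs, n_a * length(b) - u_a_obs), p = min(1, p))
}

# independent BH step-up computed from the definition
bh_manual <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# one count-level null "pipeline run" for the USCG control: Poisson counts
# at a constant concentration -> RPKSM -> control
uscg_null_run <- function(seed, fold = 1) {
  cfg <- truth_config(
    n_families = 5,
    S_range = c(1L, 3L),
    length_range = c(150L, 400L),
    cohort_design = tibble::tibble(
      cohort = rep(c("c1", "c2", "c3"), each = 2),
      group = rep(c("ctrl", "dis"), 3),
      role = rep(c("control", "case"), 3),
      n = rep(20L, 6)
    ),
    fold_changes = if (fold != 1) list(dis = fold) else list(),
    seed = seed
  )
  samples <- simulate_cohort_design(cfg)
  fams <- withr::with_seed(seed, tibble::tibble(
    family_id = paste0("USCG", 1:5),
    S = sample(1:3, 5, TRUE),
    mean_length_nt = 3 * sample(150:400, 5),
    baseline = exp(runif(5, log(100), log(1000)))
  ))
  counts <- withr::with_seed(seed + 1L, {
    tidyr::expand_grid(fams, samples) |>
      dplyr::mutate(
        a = baseline * ifelse(role == "case", fold, 1),
        mu = a * S * (mean_length_nt / 1000) * library_size / 1e6,
        count = rpois(dplyr::n(), mu),
        rpksm = compute_rpksm(count, mean_length_nt, S, library_size)
      )
  })
  uscg_control(counts, samples, fams$family_id)
}
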