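# Localization census: dedup semantics, assignment modes, size tables,
# density stratification, and the documented invariants.

map_from <- function(x, y, w = 7000, h = 7000, frame = NULL) {
  df <- data.frame(x_nm = x, y_nm = y)
  if (!is.null(frame)) df$frame <- frame
  localization_map(df, w, h)
}

test_that("localization map enforces the half-open ROI and I/O round-trips", {
  expect_error(map_from(c(0, 7000), c(1, 1)), "half-open")
  m <- map_from(c(0, 10, 20), c(5, 5, 5))
  expect_equal(n_points(m), 3L)

  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x_nm,y_nm", "10,10", "7000,5", "20,30"), path)
  expect_message(m2 <- read_localizations(path), "dropped 1")
  expect_equal(n_points(m2), 2L)

  writeLines("x_nm,y_nm", path)
  empty <- read_localizations(path)
  expect_equal(n_points(empty), 0L)
  cen <- census(assign_complexes(empty), empty)
  expect_equal(cen$total_receptors, 0L)
  expect_equal(cen$density_per_um2, 0)
  expect_equal(cen$density_class, "low")

  writeLines(c("x_nm,y_nm", "10,oops"), path)
  expect_error(read_localizations(path), "malformed")

  write_localizations(m, path)
  expect_equal(read_localizations(path)$points$x_nm, m$points$x_nm)
})

test_that("dedup follows the greedy keep-first rule", {
  # 15 nm apart: one survivor; 25 nm: both survive
  expect_equal(n_points(deduplicate(map_from(c(0, 15), c(0, 0)))), 1L)
  expect_equal(n_points(deduplicate(map_from(c(0, 25), c(0, 0)))), 2L)
  # chain 0, 15, 30: greedy is non-transitive, keeps 0 and 30
  chain <- deduplicate(map_from(c(0, 15, 30), c(0, 0, 0)))
  expect_equal(sort(chain$points$x_nm), c(0, 30))
  # boundary: exactly 20 nm is NOT discounted (strictly-within rule)
  expect_equal(n_points(deduplicate(map_from(c(0, 20), c(0, 0)))), 2L)
})

test_that("dedup is idempotent, order-independent, and matches brute force", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(5:30, 1)
    x <- runif(n, 0, 200); y <- runif(n, 0, 200)
    m <- map_from(x, y)
    d1 <- deduplicate(m)
    expect_identical(deduplicate(d1)$points, d1$points)
    # shuffled input gives the same retained point set
    perm <- sample(n)
    d2 <- deduplicate(map_from(x[perm], y[perm]))
    expect_equal(sort(d1$points$x_nm), sort(d2$points$x_nm))
    # brute-force oracle on canonically sorted points
    o <- order(x, y)
    keep <- oracle_dedup_keep(x[o], y[o], 20)
    expect_equal(d1$points$x_nm, x[o][keep])
  }
})

test_that("assignment modes reproduce the hand-traced collinear example", {
  # 40 nm apart: a dimer in both modes
  a <- assign_complexes(map_from(c(0, 40), c(0, 0)))
  expect_equal(a$sizes, 2L)
  # 0, 40, 80: greedy seed -> dimer {0,40} + monomer {80};
  # single linkage -> one trimer
  m3 <- map_from(c(0, 40, 80), c(0, 0, 0))
  g <- assign_complexes(m3, census_config(assignment_mode = "greedy_seed"))
  expect_equal(sort(g$sizes), c(1L, 2L))
  expect_equal(g$points$complex_id[g$points$x_nm %in% c(0, 40)],
               c(1L, 1L))
  s <- assign_complexes(m3, census_config(assignment_mode = "single_linkage"))
  expect_equal(s$sizes, 3L)
  # boundary: exactly 50 nm joins (inclusive rule)
  b <- assign_complexes(map_from(c(0, 50), c(0, 0)))
  expect_equal(b$sizes, 2L)
})

test_that("both assignment modes match brute-force oracles on random maps", {
  n_mismatch_greedy <- 0L
  n_mismatch_link <- 0L
  dominance_ok <- TRUE
  for (seed in 1:300) {
    set.seed(seed)
    n <- sample(2:12, 1)
    x <- runif(n, 0, 500); y <- runif(n, 0, 500)
    m <- map_from(x, y)
    cfg_g <- census_config(assignment_mode = "greedy_seed")
    cfg_s <- census_config(assignment_mode = "single_linkage")
    g <- assign_complexes(m, cfg_g)
    s <- assign_complexes(m, cfg_s)
    # oracle operates on the same canonical order (x then y here)
    o <- order(x, y)
    og <- oracle_greedy_assign(x[o], y[o], 50)
    os <- oracle_single_linkage(x[o], y[o], 50)
    if (!identical(sizes_of(g$points$complex_id), sizes_of(og)))
      n_mismatch_greedy <- n_mismatch_greedy + 1L
    if (!identical(sizes_of(s$points$complex_id), sizes_of(os)))
      n_mismatch_link <- n_mismatch_link + 1L
    # conservation + mode dominance
    expect_equal(sum(g$sizes), n)
    expect_equal(sum(s$sizes), n)
    if (length(s$sizes) > length(g$sizes)) dominance_ok <- FALSE
  }
  expect_equal(n_mismatch_greedy, 0L)
  expect_equal(n_mismatch_link, 0L)
  expect_true(dominance_ok)
})

test_that("census arithmetic, pooling and density classes are exact", {
  # dimer + monomer: total 3, monomer 33.3%, associated 66.7%
  m <- map_from(c(0, 40, 500), c(0, 0, 500))
  cen <- census(assign_complexes(m), m)
  expect_equal(cen$total_receptors, 3L)
  expect_equal(cen$pct_monomer, 100 / 3)
  expect_equal(cen$pct_associated, 200 / 3)
  expect_equal(sum(cen$pct_by_size), 100, tolerance = 1e-9)
  # pooling: a 12-mer lands in the 10+ bin
  xs <- seq(0, by = 10, length.out = 12)
  m12 <- map_from(xs, rep(0, 12))
  cen12 <- census(assign_complexes(
    m12, census_config(assignment_mode = "single_linkage")), m12)
  expect_equal(unname(cen12$count_by_size["10+"]), 1L)
  expect_equal(unname(cen12$pct_by_size["10+"]), 100)
  expect_equal(cen12$total_receptors, 12L)
})

test_that("censuses are invariant to input row order", {
  set.seed(77)
  n <- 200
  x <- runif(n, 0, 7000); y <- runif(n, 0, 7000)
  m1 <- map_from(x, y)
  perm <- sample(n)
  m2 <- map_from(x[perm], y[perm])
  for (mode in c("greedy_seed", "single_linkage")) {
    cfg <- census_config(assignment_mode = mode)
    c1 <- census(assign_complexes(deduplicate(m1), cfg), deduplicate(m1), cfg)
    c2 <- census(assign_complexes(deduplicate(m2), cfg), deduplicate(m2), cfg)
    expect_equal(c1$count_by_size, c2$count_by_size)
  }
})

test_that("well-separated noise-free maps reproduce the composition exactly", {
  truth <- c("1" = 20, "2" = 12, "3" = 6, "5" = 2)
  sim <- simulate_localizations(palm_sim_config(
    truth, cluster_radius_nm = 10, loc_error_sd_nm = 0, blink_rate = 0,
    min_center_sep_nm = 400, seed = 13))
  cen <- census(assign_complexes(sim$map), sim$map)
  got <- cen$count_by_size[cen$count_by_size > 0]
  expect_equal(got, c("1" = 20L, "2" = 12L, "3" = 6L, "5" = 2L))
})

test_that("density stratification groups by the >100/um2 rule", {
  mk <- function(n_per_complex) {
    sim <- simulate_localizations(palm_sim_config(
      stats::setNames(n_per_complex, "1"), loc_error_sd_nm = 0,
      blink_rate = 0, seed = n_per_complex))
    census(assign_complexes(sim$map), sim$map)
  }
  hi <- mk(7350)   # 7350 / 49 um2 = 150 /um2
  lo <- mk(2450)   # 50 /um2
  expect_equal(hi$density_per_um2, 150)
  expect_equal(hi$density_class, "high")
  expect_equal(lo$density_per_um2, 50)
  expect_equal(lo$density_class, "low")
  strat <- stratify_by_density(list(hi, lo, lo))
  expect_equal(sum(strat$n_roi), 3L)
  expect_equal(strat$n_roi[strat$density_class == "low"], 2L)
  expect_error(stratify_by_density(list()), "at least one")
})
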