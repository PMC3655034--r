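test_that("bin counting matches a hand-count oracle on a one-observation input", {
  tab <- rama_table_from_angles("ALA", -57.5, -47.5, pseudocount = 1)
  # the observed bin holds (1 + 1) / (1 + 360*360); all others 1 / (1 + 360*360)
  expect_equal(rama_prob(tab, "ALA", -57.5, -47.5), 2 / 129601)
  expect_equal(rama_prob(tab, "ALA", 10, 10), 1 / 129601)
  # half-open [k, k+1) binning: -57.01 and -57.99 share the bin of -57.5,
  # -57.0 starts the next bin up
  expect_equal(rama_prob(tab, "ALA", -57.01, -47.5), 2 / 129601)
  expect_equal(rama_prob(tab, "ALA", -57.0, -47.5), 1 / 129601)
  # per-type normalization
  expect_equal(sum(sapply(0:359, function(i)
    sum(rama_prob(tab, "ALA", -180 + i, -180 + 0:359)))), 1, tolerance = 1e-9)
})

test_that("log-odds obey their closed forms", {
  # never-observed type: uniform grid, every bin 1/129600, score 0
  tab <- rama_table_from_angles("ALA", -57.5, -47.5, pseudocount = 1)
  expect_equal(rama_prob(tab, "TRP", 33, -121), 1 / 129600)
  expect_equal(rama_log_odds(tab, "TRP", 33, -121), 0)
  expect_equal(rama_log_odds(uniform_rama, "ALA", -60, -40), 0)
  # all mass in one bin: ln(129600) in the limit of zero pseudocount
  conc <- rama_table_from_angles(rep("GLY", 5000), rep(10.5, 5000),
                                 rep(20.5, 5000), pseudocount = 1e-12)
  expect_equal(rama_log_odds(conc, "GLY", 10.5, 20.5), log(129600),
               tolerance = 1e-9)
  # arbitrary table: score equals ln P - ln(1/129600) by direct arithmetic
  set.seed(4)
  tab2 <- rama_table_from_angles(rep("SER", 200), runif(200, -180, 180),
                                 runif(200, -180, 180), pseudocount = 0.5)
  for (q in 1:5) {
    phi <- runif(1, -180, 180); psi <- runif(1, -180, 180)
    expect_equal(rama_log_odds(tab2, "SER", phi, psi),
                 log(rama_prob(tab2, "SER", phi, psi)) - log(1 / 129600),
                 tolerance = 1e-12)
  }
  # piecewise constant on 1-degree bins
  expect_equal(rama_log_odds(tab2, "SER", 10.0, 20.0),
               rama_log_odds(tab2, "SER", 10.99, 20.99))
  # wrap immunity: theta and theta + 360 land in the same bin
  expect_equal(rama_log_odds(tab2, "SER", 10.3 - 360, 20.7 + 360),
               rama_log_odds(tab2, "SER", 10.3, 20.7))
  expect_error(rama_log_odds(tab2, "SER", NA, 10), "undefined")
})

test_that("tables serialize exactly", {
  set.seed(9)
  tab <- rama_table_from_angles(sample(c("ALA", "GLY", "TRP"), 300, TRUE),
                                runif(300, -180, 180), runif(300, -180, 180),
                                pseudocount = 0.25)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_rama_table(tab, path)
  tab2 <- read_rama_table(path)
  expect_identical(tab2$pseudocount, tab$pseudocount)
  for (aa in names(tab$counts)) {
    expect_identical(tab2$counts[[aa]], tab$counts[[aa]])
  }
  expect_identical(rama_prob(tab2, "GLY", -33.2, 81.9),
                   rama_prob(tab, "GLY", -33.2, 81.9))
})

test_that("rotamer libraries are read from both supported formats", {
  fb <- read_rotamer_library()
  expect_s3_class(fb, "rotamer_table")
  expect_false(attr(fb, "bbdep"))
  for (aa in unique(fb$aa)) {
    rows <- get_rotamers(fb, aa)
    expect_equal(sum(rows$prob), 1, tolerance = 1e-6)
    k <- n_chi(aa)
    expect_true(all(as.matrix(rows[, paste0("s", seq_len(k))]) > 0))
  }
  # Dunbrack-style backbone-dependent text (synthetic excerpt)
  dun <- c(
    "# synthetic excerpt in bbdep text format",
    "SER  -60 -40   120   1 0 0 0  0.55    62.1    0.0    0.0    0.0   9.5  0.0  0.0  0.0",
    "SER  -60 -40    80   2 0 0 0  0.45   -64.8    0.0    0.0    0.0  10.1  0.0  0.0  0.0",
    "SER  -180 180   50   1 0 0 0  0.70   180.0    0.0    0.0    0.0  11.0  0.0  0.0  0.0")
  path <- withr::local_tempfile(fileext = ".lib")
  writeLines(dun, path)
  bb <- read_rotamer_library(path)
  expect_true(attr(bb, "bbdep"))
  near <- get_rotamers(bb, "SER", -58, -42)
  expect_equal(nrow(near), 2L)
  expect_equal(sum(near$prob), 1)
  expect_equal(sort(near$m1), c(-64.8, 62.1))
  far <- get_rotamers(bb, "SER", -179, 179)
  expect_equal(far$m1, 180.0)
})

test_that("chi log-odds follow the rotamer-density closed form", {
  expect_equal(chi_log_odds(read_rotamer_library(), "ALA", -60, -40), 0)
  expect_equal(chi_log_odds(read_rotamer_library(), "GLY", -60, -40), 0)
  # single-rotamer toy table: hand arithmetic at and off the mean
  toy_rot <- structure(
    data.frame(aa = "SER", phi_bin = NA, psi_bin = NA, prob = 1,
               m1 = 60, m2 = NA, m3 = NA, m4 = NA,
               s1 = 10, s2 = NA, s3 = NA, s4 = NA, nchi = 1L),
    class = c("rotamer_table", "data.frame"), bbdep = FALSE)
  expect_equal(chi_log_odds(toy_rot, "SER", chis = 60),
               log(1 * stats::dnorm(0, 0, 10) / (1 / 360)))
  expect_equal(chi_log_odds(toy_rot, "SER", chis = 75),
               log(stats::dnorm(15, 0, 10)) - log(1 / 360))
  # wrapped matching: 179 vs mean -179 is 2 degrees apart
  toy2 <- toy_rot; toy2$m1 <- -179
  expect_equal(chi_log_odds(toy2, "SER", chis = 179),
               log(stats::dnorm(2, 0, 10)) - log(1 / 360))
  # two rotamers: nearest mean under wrapped distance wins
  toy3 <- structure(
    data.frame(aa = "SER", phi_bin = NA, psi_bin = NA, prob = c(0.7, 0.3),
               m1 = c(60, -170), m2 = NA, m3 = NA, m4 = NA,
               s1 = c(10, 10), s2 = NA, s3 = NA, s4 = NA, nchi = 1L),
    class = c("rotamer_table", "data.frame"), bbdep = FALSE)
  expect_equal(chi_log_odds(toy3, "SER", chis = 175),
               log(0.3 * stats::dnorm(-15, 0, 10) / (1 / 360)))
  expect_error(chi_log_odds(read_rotamer_library(), "XXX", chis = 10),
               "unknown")
})
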