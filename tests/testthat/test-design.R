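test_that("sequence recovery counts identities and never matches gaps", {
  expect_equal(sequence_recovery("GATTACA", "GATTACA"), 100)
  expect_equal(sequence_recovery("AAAA", "AAAG"), 75)
  expect_equal(sequence_recovery("AAAA", "GGAA", positions = c(1, 2)), 0)
  expect_equal(sequence_recovery("A-A-", "A-A-"), 50)  # gaps never match
  expect_error(sequence_recovery("AAA", "AAAA"), "length mismatch")
  expect_error(sequence_recovery("AAA", "AAA", positions = 4), "out of range")
})

test_that("column distributions renormalize over non-gap residues", {
  al <- make_msa("AC", "AC", "CA", "CA")
  p <- column_distribution(al, 1)
  expect_equal(unname(p[c("A", "C")]), c(0.5, 0.5))
  expect_equal(sum(p), 1)
  al2 <- make_msa("A-", "--", "A-", "--")
  p2 <- column_distribution(al2, 1)
  expect_equal(unname(p2["A"]), 1.0)
  empty <- column_distribution(al2, 2)
  expect_true(isTRUE(attr(empty, "empty")))
  al3 <- msa("one", paste(AA_ALPHABET, collapse = ""))
  al3_cols <- vapply(1:20, function(j) column_distribution(al3, j)[j],
                     numeric(1))
  expect_equal(al3_cols, rep(1, 20), ignore_attr = TRUE)
})

test_that("entropy, JS divergence and profile similarity hit closed forms", {
  onehot <- function(i) { v <- numeric(20); v[i] <- 1; v }
  expect_equal(shannon_entropy(onehot(1)), 0)
  expect_equal(shannon_entropy(rep(0.05, 20)), log2(20), tolerance = 1e-12)
  expect_equal(shannon_entropy(c(0.5, 0.5, rep(0, 18))), 1.0)

  expect_equal(js_divergence(onehot(3), onehot(3)), 0)
  expect_equal(js_divergence(onehot(1), onehot(2)), 1.0, tolerance = 1e-12)
  expect_equal(js_divergence(c(1, 0), c(0.5, 0.5)),
               1.5 - 0.75 * log2(3), tolerance = 1e-9)  # = 0.31128

  u <- uniform_background()
  expect_equal(profile_similarity(u, u, u), 0.5, tolerance = 1e-12)
  # identical one-hots maximally far from a disjoint background
  bg <- c(0, 1, rep(0, 18))
  expect_equal(profile_similarity(onehot(1), onehot(1), bg), 1.0,
               tolerance = 1e-12)
  # cross-check against direct formula evaluation
  p <- onehot(1)
  want <- 0.5 * (1 + js_divergence(p, u))
  expect_equal(profile_similarity(p, p, u), want, tolerance = 1e-12)
  expect_gte(want, 0.5)
})

test_that("average profile similarity equals per-column recomputation", {
  set.seed(41)
  nat <- simulate_msa(30, 6, seed = 42)
  des <- simulate_msa(30, 6, seed = 43)
  res <- average_profile_similarity(nat, des)
  manual <- vapply(1:6, function(j) {
    profile_similarity(column_distribution(nat, j),
                       column_distribution(des, j))
  }, numeric(1))
  expect_equal(res$per_column, manual, tolerance = 1e-12)
  expect_equal(res$mean, mean(manual), tolerance = 1e-12)
  self <- average_profile_similarity(nat, nat)
  expect_true(all(self$per_column >= 0.5 - 1e-12))
  expect_error(average_profile_similarity(nat, simulate_msa(10, 5, seed = 1)),
               "different lengths")
})

test_that("burial classification counts C-beta neighbors with strict thresholds", {
  lone <- simulate_structure(1, "line")
  b <- classify_burial(lone)
  expect_equal(b$n_neighbors, 0L)
  expect_identical(b$burial, "exposed")

  line <- simulate_structure(10, "line", spacing = 10)
  expect_true(all(classify_burial(line)$burial == "exposed"))

  # 16 residues all within 8 A: 15 neighbors each -> buried
  cl16 <- simulate_structure(16, "cluster", seed = 5)
  b16 <- classify_burial(cl16)
  expect_true(all(b16$n_neighbors == 15L))
  expect_true(all(b16$burial == "buried"))

  # 15 residues: count 14 is NOT buried (strictly greater than 14)
  cl15 <- simulate_structure(15, "cluster", seed = 5)
  b15 <- classify_burial(cl15)
  expect_true(all(b15$n_neighbors == 14L))
  expect_true(all(b15$burial == "intermediate"))

  # 9 neighbors is intermediate, 8 is exposed
  cl10 <- simulate_structure(10, "cluster", seed = 6)
  expect_true(all(classify_burial(cl10)$burial == "intermediate"))
  cl9 <- simulate_structure(9, "cluster", seed = 6)
  expect_true(all(classify_burial(cl9)$burial == "exposed"))
})

test_that("neighbor counts match a brute-force pairwise-distance oracle", {
  set.seed(51)
  df <- data.frame(chain = "A", resno = 1:40, icode = "", resname = "ALA",
                   atom = "CB",
                   x = runif(40, 0, 25), y = runif(40, 0, 25),
                   z = runif(40, 0, 25), stringsAsFactors = FALSE)
  s <- structure_coords(df)
  got <- classify_burial(s)
  want <- vapply(1:40, function(i) {
    sum(vapply(setdiff(1:40, i), function(j) {
      sqrt(sum((df[i, c("x", "y", "z")] - df[j, c("x", "y", "z")])^2)) <= 8
    }, logical(1)))
  }, numeric(1))
  expect_equal(got$n_neighbors, as.integer(want))
})

test_that("glycine falls back to C-alpha for neighbor counting", {
  df <- data.frame(chain = "A", resno = c(1, 1, 2), icode = "",
                   resname = c("GLY", "GLY", "ALA"),
                   atom = c("N", "CA", "CB"),
                   x = c(50, 0, 3), y = 0, z = 0, stringsAsFactors = FALSE)
  b <- classify_burial(structure_coords(df))
  expect_equal(nrow(b), 2)
  expect_equal(b$n_neighbors, c(1L, 1L))  # CA(gly) at 3 A from CB(ala)
})

test_that("composition percentages partition to 100 and match hand counts", {
  al <- make_msa("AAAA", "AAAA")
  comp <- composition_by_category(al)
  expect_equal(unname(comp["nonpolar"]), 100)
  expect_equal(sum(comp), 100)

  al2 <- make_msa("ASK", "ASK")
  comp2 <- composition_by_category(al2)
  expect_equal(unname(comp2), rep(100 / 3, 3), tolerance = 1e-9)

  # per-amino-acid mode against explicit counting
  al3 <- make_msa("AAC", "AC-", "CCX")
  aa <- composition_by_category(al3, categories = NULL)
  expect_equal(unname(aa["A"]), 100 * 3 / 7, tolerance = 1e-9)
  expect_equal(unname(aa["C"]), 100 * 4 / 7, tolerance = 1e-9)
  expect_equal(sum(aa), 100)

  expect_error(composition_by_category(al, categories = list(a = "A")),
               "partition")
  set.seed(61)
  rnd <- simulate_msa(25, 9, seed = 62)
  expect_equal(sum(composition_by_category(rnd)), 100, tolerance = 1e-9)
})
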