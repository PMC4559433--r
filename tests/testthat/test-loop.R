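test_that("Kabsch superposition recovers rigid transforms exactly", {
  set.seed(101)
  ref <- matrix(rnorm(30), ncol = 3)
  # identity input
  fit <- kabsch_superpose(ref, ref)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)
  expect_equal(fit$translation, rep(0, 3), tolerance = 1e-9)
  expect_lt(fit$rmsd, 1e-9)
  # a rotated + translated copy superposes to rmsd 0
  for (i in 1:5) {
    R <- random_rotation(); t <- rnorm(3, sd = 10)
    mob <- sweep(ref %*% R, 2, t, "+")
    fit <- kabsch_superpose(mob, ref)
    expect_lt(fit$rmsd, 1e-9)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
    moved <- sweep(mob %*% fit$rotation, 2, fit$translation, "+")
    expect_lt(max(abs(moved - ref)), 1e-6)
  }
  expect_error(kabsch_superpose(ref[1:2, ], ref[1:2, ]), "at least 3")
})

test_that("Kabsch is optimal against randomly sampled rotations", {
  set.seed(102)
  for (i in 1:5) {
    A <- matrix(rnorm(30), ncol = 3)
    B <- matrix(rnorm(30), ncol = 3)
    best <- kabsch_superpose(A, B)$rmsd
    Ac <- scale(A, scale = FALSE); Bc <- scale(B, scale = FALSE)
    rand <- vapply(1:500, function(k) {
      sqrt(mean(rowSums((Ac %*% random_rotation() - Bc)^2)))
    }, numeric(1))
    expect_lte(best, min(rand) + 1e-9)
  }
})

test_that("loop RMSD measures loop displacement in the native frame", {
  nat <- simulate_protein_backbone(20)
  loop <- data.frame(chain = "A", resno = 8:12, icode = "")
  expect_equal(loop_rmsd(nat, nat, loop), 0, tolerance = 1e-12)
  # uniform 1 A loop translation with an exact frame
  mod <- as.data.frame(nat)
  sel <- mod$resno %in% 8:12
  mod$x[sel] <- mod$x[sel] + 1
  expect_equal(loop_rmsd(structure_coords(mod), nat, loop), 1.0,
               tolerance = 1e-9)
  # missing backbone atom errors with the residue named
  broken <- as.data.frame(nat)
  broken <- broken[!(broken$resno == 9 & broken$atom == "CA"), ]
  expect_error(loop_rmsd(structure_coords(broken), nat, loop), "A\\|9\\|\\|CA")
  # loop not present in native
  expect_error(loop_rmsd(nat, nat, data.frame(chain = "A", resno = 99,
                                              icode = "")), "not in native")
})

test_that("loop RMSD is invariant under rigid transforms of the model", {
  nat <- simulate_protein_backbone(25)
  loop <- data.frame(chain = "A", resno = 10:14, icode = "")
  case <- simulate_loop_ensemble(nat, loop, 1, perturbation_scale = 1.2,
                                 seed = 103)
  model <- case$models[[1]]
  base <- loop_rmsd(model, nat, loop)
  set.seed(104)
  for (i in 1:20) {
    moved <- transform_structure(model, random_rotation(), rnorm(3, sd = 20))
    expect_equal(loop_rmsd(moved, nat, loop), base, tolerance = 1e-9)
  }
})

test_that("loop RMSD equals an independent fit-then-measure oracle", {
  nat <- simulate_protein_backbone(25)
  loop <- data.frame(chain = "A", resno = 10:14, icode = "")
  bb <- c("N", "CA", "C", "O")
  case <- simulate_loop_ensemble(nat, loop, 3, perturbation_scale = 0.8,
                                 seed = 105)
  natdf <- as.data.frame(nat)
  for (model in case$models) {
    moddf <- as.data.frame(model)
    frame_sel <- !(natdf$resno %in% 10:14) & natdf$atom %in% bb
    loop_sel <- natdf$resno %in% 10:14 & natdf$atom %in% bb
    # oracle: separate fit (on frame) and measure (on loop)
    fit <- kabsch_superpose(as.matrix(moddf[frame_sel, c("x", "y", "z")]),
                            as.matrix(natdf[frame_sel, c("x", "y", "z")]))
    moved <- sweep(as.matrix(moddf[loop_sel, c("x", "y", "z")]) %*%
                     fit$rotation, 2, fit$translation, "+")
    want <- sqrt(mean(rowSums((moved -
                                 as.matrix(natdf[loop_sel,
                                                 c("x", "y", "z")]))^2)))
    expect_equal(loop_rmsd(model, nat, loop), want, tolerance = 1e-9)
  }
})

test_that("case metrics summarize energies and RMSDs as specified", {
  nat <- simulate_protein_backbone(20)
  loop <- data.frame(chain = "A", resno = 8:12, icode = "")
  # five models with known uniform loop displacements
  disp <- c(2.0, 0.5, 3.0, 0.9, 4.0)
  models <- lapply(disp, function(d) {
    df <- as.data.frame(nat)
    sel <- df$resno %in% 8:12
    df$x[sel] <- df$x[sel] + d
    structure_coords(df)
  })
  case <- loop_case("worked", nat, loop, models, energies = 1:5)
  cm <- case_metrics(case)
  expect_equal(cm$rmsd_lowest_energy, 2.0, tolerance = 1e-9)
  expect_equal(cm$rmsd_best_of_5_lowest, 0.5, tolerance = 1e-9)
  expect_equal(cm$pct_subangstrom, 40.0)
  # all models identical to native
  perfect <- loop_case("perfect", nat, loop, list(nat, nat, nat), 1:3)
  pm <- case_metrics(perfect)
  expect_equal(pm$rmsd_lowest_energy, 0, tolerance = 1e-12)
  expect_true(is_undefined_metric(pm$rmsd_best_of_5_lowest))
  expect_equal(pm$pct_subangstrom, 100)
})

test_that("case metrics match a brute-force sorting oracle", {
  nat <- simulate_protein_backbone(22)
  loop <- data.frame(chain = "A", resno = 9:13, icode = "")
  for (s in 1:3) {
    case <- simulate_loop_ensemble(nat, loop, 8, perturbation_scale = 0.7,
                                   energy_rmsd_correlation = 0.5,
                                   seed = 300 + s)
    cm <- case_metrics(case)
    r <- cm$rmsds; e <- case$energies
    expect_equal(r, case$true_rmsds, tolerance = 1e-9)
    ord <- sort.int(e, index.return = TRUE)$ix
    expect_identical(cm$rmsd_lowest_energy, r[ord[1]])
    expect_identical(cm$rmsd_best_of_5_lowest, min(r[ord[1:5]]))
    expect_equal(cm$pct_subangstrom, 100 * sum(r < 1) / 8)
  }
})

test_that("benchmark medians follow the even-length median rule", {
  mk <- function(le, b5, pct) list(rmsd_lowest_energy = le,
                                   rmsd_best_of_5_lowest = b5,
                                   pct_subangstrom = pct, n_models = 10)
  single <- benchmark_metrics(list(mk(1.2, 0.8, 30)))
  expect_equal(single$median_rmsd_lowest_energy, 1.2)
  three <- benchmark_metrics(list(mk(1, 1, 0), mk(2, 2, 10), mk(3, 3, 20)))
  expect_equal(three$median_pct_subangstrom, 10)
  four <- benchmark_metrics(list(mk(1, 1, 0), mk(2, 2, 10),
                                 mk(3, 3, 20), mk(4, 4, 50)))
  expect_equal(four$median_rmsd_lowest_energy, 2.5)
  expect_equal(four$median_pct_subangstrom, 15)
  expect_error(benchmark_metrics(list()), "no cases")
})

test_that("crystal-contact filter counts loop residues near symmetry mates", {
  nat <- simulate_protein_backbone(20)
  loop <- data.frame(chain = "A", resno = 8:13, icode = "")  # 6 residues
  # no symmetry mates: pass with warning
  empty <- structure_coords(data.frame(chain = character(0),
                                       resno = integer(0), icode = character(0),
                                       resname = character(0),
                                       atom = character(0),
                                       x = numeric(0), y = numeric(0),
                                       z = numeric(0)))
  expect_warning(res <- crystal_contact_filter(loop, nat, empty), "empty")
  expect_true(res$pass)
  expect_equal(res$n_contact_residues, 0L)
  # one mate atom 5 A from each loop CA: 6 contacts -> fail at max 5
  natdf <- as.data.frame(nat)
  cas <- natdf[natdf$resno %in% 8:13 & natdf$atom == "CA", ]
  mates <- structure_coords(data.frame(chain = "B", resno = seq_len(6),
                                       icode = "", resname = "ALA", atom = "CB",
                                       x = cas$x, y = cas$y + 5, z = cas$z))
  res2 <- crystal_contact_filter(loop, nat, mates)
  expect_false(res2$pass)
  expect_equal(res2$n_contact_residues, 6L)
  # a mate atom at exactly the 6 A cutoff still counts
  one <- structure_coords(data.frame(chain = "B", resno = 1, icode = "",
                                     resname = "ALA", atom = "CB",
                                     x = cas$x[1], y = cas$y[1] + 6,
                                     z = cas$z[1]))
  res3 <- crystal_contact_filter(data.frame(chain = "A", resno = 8,
                                            icode = ""), nat, one)
  expect_equal(res3$n_contact_residues, 1L)
  expect_true(res3$pass)
  # hydrogens are ignored
  h <- structure_coords(data.frame(chain = "B", resno = 1, icode = "",
                                   resname = "ALA", atom = "H",
                                   x = cas$x[1], y = cas$y[1] + 1, z = cas$z[1]))
  expect_warning(res4 <- crystal_contact_filter(loop, nat, h), "empty")
  expect_equal(res4$n_contact_residues, 0L)
})

test_that("loop spec strings parse to residue tables", {
  sp <- parse_loop_spec("A:153-164")
  expect_equal(nrow(sp), 12)
  expect_equal(sp$resno[1], 153)
  expect_identical(unique(sp$chain), "A")
  expect_error(parse_loop_spec("nonsense"), "cannot parse")
})
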