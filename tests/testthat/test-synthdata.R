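test_that("the template is complete, C2-symmetric and deterministic", {
  tmpl <- make_template()
  tr <- as_trajectory(tmpl)
  # every descriptor evaluates on the template
  expect_s3_class(dbh_dihedral_series(tr), "descriptor_series")
  expect_s3_class(hinge_angle_series(tr), "descriptor_series")
  expect_s3_class(interchain_ca_distance_series(tr), "descriptor_series")
  expect_s3_class(site2_gap_series(tr, "A"), "descriptor_series")
  # exact C2 symmetry: equal hinge angles, equal chain geometry
  hA <- hinge_angle_series(tr, chain = "A")$values
  hB <- hinge_angle_series(tr, chain = "B")$values
  expect_equal(hA, hB, tolerance = 1e-10)
  a <- tmpl$coords[tmpl$atoms$chain == "A", ]
  b <- tmpl$coords[tmpl$atoms$chain == "B", ]
  expect_equal(b, a %*% diag(c(-1, -1, 1)), tolerance = 1e-12)
  # deterministic
  expect_identical(make_template(), tmpl)
  expect_error(make_template(residues_per_chain = 90), class = "mnt_param_error")
})

test_that("preset parameters carry the reported state statistics", {
  apo <- preset_params("apo")
  expect_equal(apo$dbh_mean, 64.6); expect_equal(apo$dbh_sd, 12.5)
  expect_equal(apo$hinge_mean, 170.3); expect_equal(apo$hinge_sd, 4.1)
  expect_equal(apo$lys41_mean, 37.8); expect_equal(apo$lys41_sd, 2.8)
  mn <- preset_params("mn")
  expect_equal(mn$dbh_mean, 36.5); expect_equal(mn$dbh_sd, 7.3)
  expect_equal(mn$hinge_mean, 169.5); expect_equal(mn$lys41_mean, 37.2)
  zn <- preset_params("zn")
  expect_equal(zn$hinge_mean, 173.1); expect_equal(zn$hinge_sd, 3.5)
  expect_equal(unname(zn$provenance["hinge"]), "reported")
  expect_equal(unname(zn$provenance["dbh"]), "assumed")
  mut <- preset_params("mutant")
  expect_true(all(mut$provenance == "assumed"))
  expect_lt(abs(mut$dbh_mean - mn$dbh_mean), 10)   # mutant behaves Mn-like
  expect_error(preset_params("cobalt"))
})

test_that("exact posing hits drawn targets to machine precision before jitter", {
  p <- synthetic_params(n_frames = 20, seed = 9, dbh_mean = 50, dbh_sd = 0,
                        hinge_sd = 0, lys41_sd = 0, jitter_sd = 0)
  tr <- generate_ensemble(p)
  expect_lt(max(abs(dbh_dihedral_series(tr)$values - 50)), 1e-6)
  expect_lt(max(abs(hinge_angle_series(tr)$values - p$hinge_mean)), 1e-6)
  expect_lt(max(abs(interchain_ca_distance_series(tr)$values - p$lys41_mean)), 1e-6)
  # with nonzero sds the drawn targets are still hit exactly frame by frame
  set.seed(99)
  p2 <- synthetic_params(n_frames = 30, seed = 10, jitter_sd = 0)
  tr2 <- generate_ensemble(p2)
  set.seed(p2$seed)
  dbh_t <- mntrdyn:::ar1_series(30, p2$dbh_mean, p2$dbh_sd, 0)
  expect_equal(dbh_dihedral_series(tr2)$values, dbh_t, tolerance = 1e-9)
})

test_that("generation is bitwise deterministic in params and seed", {
  p <- preset_params("apo", n_frames = 15, seed = 42)
  expect_identical(generate_ensemble(p)$xyz, generate_ensemble(p)$xyz)
  p2 <- preset_params("apo", n_frames = 15, seed = 43)
  expect_false(identical(generate_ensemble(p)$xyz, generate_ensemble(p2)$xyz))
})

test_that("descriptor distributions recover preset targets at n = 3000", {
  se <- function(sd, n) sd / sqrt(n)
  for (st in c("apo", "mn")) {
    p <- preset_params(st, n_frames = 3000, seed = 21)
    tr <- generate_ensemble(p)
    d <- dbh_dihedral_series(tr)$values
    expect_lt(abs(mean(d) - p$dbh_mean), 4 * se(p$dbh_sd, 3000))
    h <- hinge_angle_series(tr)$values   # two-chain mean halves the variance
    expect_lt(abs(mean(h) - p$hinge_mean), 4 * se(p$hinge_sd / sqrt(2), 3000))
    l <- interchain_ca_distance_series(tr)$values
    expect_lt(abs(mean(l) - p$lys41_mean), 4 * se(p$lys41_sd, 3000))
  }
})

test_that("with ar1 = 0 frames are exchangeable; ar1 > 0 induces autocorrelation", {
  p <- preset_params("mn", n_frames = 300, seed = 31)
  tr <- generate_ensemble(p)
  d <- dbh_dihedral_series(tr)$values
  set.seed(77)
  perm <- sample(300)
  tr_p <- tr; tr_p$xyz <- tr$xyz[perm, ]
  s1 <- summarize_series(dbh_dihedral_series(tr))
  s2 <- summarize_series(dbh_dihedral_series(tr_p))
  expect_equal(unclass(s1), unclass(s2), tolerance = 1e-12)
  expect_lt(abs(cor(d[-1], d[-300])), 0.2)
  p_ar <- synthetic_params(n_frames = 600, seed = 32, ar1 = 0.8)
  d_ar <- dbh_dihedral_series(generate_ensemble(p_ar))$values
  expect_gt(cor(d_ar[-1], d_ar[-600]), 0.6)
})

test_that("generated ensembles survive a PDB round-trip with descriptors intact", {
  tr <- generate_ensemble(preset_params("apo", n_frames = 10, seed = 41))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(tr, f)
  tr2 <- read_pdb_models(f)
  expect_lt(max(abs(tr2$xyz - tr$xyz)), 1e-3)
  # descriptor error bounded by propagation of the 5e-4 coordinate rounding
  expect_lt(max(abs(dbh_dihedral_series(tr2)$values -
                    dbh_dihedral_series(tr)$values)), 0.02)
  expect_lt(max(abs(interchain_ca_distance_series(tr2)$values -
                    interchain_ca_distance_series(tr)$values)), 2e-3)
})

test_that("infeasible targets raise a generation error naming the frame", {
  p <- synthetic_params(n_frames = 3, seed = 5, lys41_mean = 0.5, lys41_sd = 0,
                        jitter_sd = 0)
  expect_error(generate_ensemble(p), "frame", class = "mnt_generation_error")
  expect_error(synthetic_params(ar1 = 1), class = "mnt_param_error")
  expect_error(synthetic_params(dbh_sd = -1), class = "mnt_param_error")
  expect_error(synthetic_params(dbh_residue_range = c(40, 50)),
               class = "mnt_param_error")
})

test_that("params serialise to JSON with provenance flags", {
  p <- preset_params("zn", n_frames = 10, seed = 2)
  f <- withr::local_tempfile(fileext = ".json")
  write_params_json(p, f)
  js <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(js$hinge_mean, 173.1)
  expect_equal(js$provenance[["dbh"]], "assumed")
})
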