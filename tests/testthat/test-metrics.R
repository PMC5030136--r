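test_that("self-assessment gives perfect metrics", {
  d <- fix_dimer()
  m <- capri_metrics(d, d)
  expect_equal(m$f_nat, 1.0)
  expect_equal(m$f_nonnat, 0.0)
  expect_equal(m$l_rms, 0, tolerance = 1e-8)
  expect_equal(m$i_rms, 0, tolerance = 1e-8)
  expect_equal(m$theta_l, 0, tolerance = 1e-6)
  expect_equal(m$d_l, 0, tolerance = 1e-8)
})

test_that("a far-displaced ligand gives f(nat) 0 and large rmsds", {
  d <- fix_dimer()
  dec <- make_decoys(d, list(decoy_spec(translation = c(0, 0, 100))))
  m <- capri_metrics(dec$models[[1]], d)
  expect_equal(m$f_nat, 0)
  expect_gt(m$l_rms, 10)
})

test_that("counted contact fractions match a constructed fixture", {
  # target: 20 native contacts; model reproduces 7 and adds 5 spurious
  mk <- function(pairs, chain_b_off) {
    do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
      rbind(atom_at(pairs[i, 1] * 10, 0, 0, chain = "A", resno = pairs[i, 1]),
            atom_at(pairs[i, 1] * 10, 4, 0, chain = "B",
                    resno = pairs[i, 2] + chain_b_off))
    }))
  }
  tpairs <- cbind(1:20, 1:20)
  target_at <- mk(tpairs, 0)
  target_at <- target_at[!duplicated(paste(target_at$chain,
                                           target_at$resno)), ]
  # model keeps contacts 1..7; residues 8..12 of B contact the wrong A
  # residue (spurious); the rest of B is far away
  model_at <- target_at
  bsel <- model_at$chain == "B"
  model_at$y[bsel & model_at$resno %in% 8:12] <- 4    # stays near...
  model_at$x[bsel & model_at$resno %in% 8:12] <-
    (model_at$resno[bsel & model_at$resno %in% 8:12] + 1) * 10  # ...wrong A
  model_at$y[bsel & model_at$resno > 12] <- 500
  tgt <- structure(list(id = "t", atoms = target_at, source = "synthetic"),
                   class = "capri_structure")
  mod <- structure(list(id = "m", atoms = model_at, source = "synthetic"),
                   class = "capri_structure")
  tc <- residue_contacts(chain_atoms(tgt, "A"), chain_atoms(tgt, "B"))
  mc <- residue_contacts(chain_atoms(mod, "A"), chain_atoms(mod, "B"))
  corr <- structure(list(pairs = data.frame(
    model_key = paste0(c(rep("A|", 20), rep("B|", 20)), c(1:20, 1:20), "|"),
    target_key = paste0(c(rep("A|", 20), rep("B|", 20)), c(1:20, 1:20), "|"),
    model_chain = c(rep("A", 20), rep("B", 20)),
    target_chain = c(rep("A", 20), rep("B", 20)),
    stringsAsFactors = FALSE), identity_fraction = 1,
    aligned_length = 40L), class = "residue_correspondence")
  fr <- native_contact_fractions(mc, tc, corr)
  expect_equal(fr$n_native, 20L)
  expect_equal(fr$n_reproduced, 7L)
  expect_equal(fr$f_nat, 0.35)
  expect_equal(fr$f_nonnat, 5 / 12)
})

test_that("degenerate target without contacts is an error", {
  d <- fix_dimer()
  apart <- d
  sel <- apart$atoms$chain == "B"
  apart$atoms$x[sel] <- apart$atoms$x[sel] + 500
  expect_error(capri_metrics(d, apart), "no contacts|degenerate")
})

test_that("pure ligand translation gives l_rms = d_l = |t| and theta 0", {
  d <- fix_dimer()
  for (t in list(c(0, 0, 6), c(2, 3, 6))) {
    dec <- make_decoys(d, list(decoy_spec(translation = t)))
    m <- capri_metrics(dec$models[[1]], d)
    expect_equal(m$l_rms, sqrt(sum(t^2)), tolerance = 1e-6)
    expect_equal(m$d_l, sqrt(sum(t^2)), tolerance = 1e-6)
    expect_equal(m$theta_l, 0, tolerance = 1e-5)
  }
})

test_that("pure ligand rotation about its centre gives theta = phi, d_l = 0", {
  d <- fix_dimer()
  dec <- make_decoys(d, list(decoy_spec(angle = 30, axis = c(0, 1, 0))))
  m <- capri_metrics(dec$models[[1]], d)
  expect_equal(m$theta_l, 30, tolerance = 1e-6)
  expect_equal(m$d_l, 0, tolerance = 1e-8)
  # direct-formula oracle for the rotational L-rms
  lig <- chain_atoms(d, "B")
  xyz <- as.matrix(lig[, c("x", "y", "z")])
  com <- colMeans(xyz)
  rot <- capriqa:::rotation_about_axis(c(0, 1, 0), 30)
  moved <- sweep(xyz, 2, com) %*% t(rot) + rep(com, each = nrow(xyz))
  expect_equal(m$l_rms, sqrt(mean(rowSums((moved - xyz)^2))),
               tolerance = 1e-6)
})

test_that("i_rms re-fit absorbs any rigid motion of the whole model", {
  d <- fix_dimer()
  tf <- rigid_transform(capriqa:::rotation_about_axis(c(1, 2, 3), 55),
                        c(4, -2, 9))
  moved <- d
  xyz <- apply_transform(tf, as.matrix(d$atoms[, c("x", "y", "z")]))
  moved$atoms$x <- xyz[, 1]; moved$atoms$y <- xyz[, 2]
  moved$atoms$z <- xyz[, 3]
  m <- capri_metrics(moved, d)
  expect_equal(m$i_rms, 0, tolerance = 1e-8)
  expect_equal(m$l_rms, 0, tolerance = 1e-8)
  expect_equal(m$f_nat, 1)
})

test_that("i_rms equals the independent quaternion-fit residual under noise", {
  d <- fix_dimer()
  corr <- map_common_residues(d, d)
  set.seed(9)
  resids <- numeric(20)
  for (k in 1:20) {
    noisy <- d
    sigma <- 0.8
    noisy$atoms$x <- noisy$atoms$x + rnorm(nrow(noisy$atoms), sd = sigma)
    noisy$atoms$y <- noisy$atoms$y + rnorm(nrow(noisy$atoms), sd = sigma)
    noisy$atoms$z <- noisy$atoms$z + rnorm(nrow(noisy$atoms), sd = sigma)
    got <- interface_rms(noisy, d, corr, "A", "B")
    # oracle: quaternion fit on the same interface atom set
    ta <- chain_atoms(d, "A"); tb <- chain_atoms(d, "B")
    ir <- interface_residues(ta, tb, 10)
    keep <- c(ir$residues_a, ir$residues_b)
    cb <- capriqa:::.common_backbone(noisy, d, corr, c("A", "B"))
    sel <- cb$target_keys %in% keep
    orc <- quaternion_superpose(cb$model[sel, ], cb$target[sel, ])
    expect_equal(got$i_rms, orc$rmsd, tolerance = 1e-6)
    resids[k] <- got$i_rms
  }
  # residual tracks the injected noise scale
  expect_gt(mean(resids), 0.8 * sqrt(3) * 0.7)
  expect_lt(mean(resids), 0.8 * sqrt(3) * 1.1)
})

test_that("i_rms never exceeds the unfitted rmsd on the same atoms", {
  d <- fix_dimer()
  dec <- make_decoys(d, list(decoy_spec(translation = c(1, 1, 2),
                                        angle = 10, axis = c(1, 0, 0))))
  mod <- dec$models[[1]]
  corr <- map_common_residues(mod, d)
  got <- interface_rms(mod, d, corr, "A", "B")
  ta <- chain_atoms(d, "A"); tb <- chain_atoms(d, "B")
  ir <- interface_residues(ta, tb, 10)
  cb <- capriqa:::.common_backbone(mod, d, corr, c("A", "B"))
  sel <- cb$target_keys %in% c(ir$residues_a, ir$residues_b)
  unfitted <- sqrt(mean(rowSums((cb$model[sel, ] - cb$target[sel, ])^2)))
  expect_lte(got$i_rms, unfitted + 1e-9)
})

test_that("decoys with known transforms reproduce their manifest", {
  d <- fix_dimer()
  specs <- list(decoy_spec(translation = c(0, 0, 2)),
                decoy_spec(translation = c(0, 4, 3)),
                decoy_spec(angle = 15, axis = c(0, 1, 0)))
  dec <- make_decoys(d, specs)
  for (k in seq_along(specs)) {
    m <- capri_metrics(dec$models[[k]], d)
    man <- dec$manifest[k, ]
    if (!is.na(man$expected_l_rms))
      expect_equal(m$l_rms, man$expected_l_rms, tolerance = 1e-6)
    if (!is.na(man$expected_theta_l))
      expect_equal(m$theta_l, man$expected_theta_l, tolerance = 1e-5)
    if (!is.na(man$expected_d_l))
      expect_equal(m$d_l, man$expected_d_l, tolerance = 1e-6)
  }
})
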