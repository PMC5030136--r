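test_that("symmetry operators must be proper rotations", {
  expect_error(symmetry_operator(diag(c(1, 1, 2))), "determinant")
  expect_error(symmetry_operator(diag(c(1, 1, -1))), "improper")
  op <- symmetry_operator(capriqa:::rotation_about_axis(c(0, 0, 1), 180),
                          c(1, 0, 0), label = "2")
  expect_s3_class(op, "symmetry_operator")
})

test_that("operator config files round-trip 4x4 transforms", {
  f <- tempfile(fileext = ".txt")
  writeLines(c("# two-fold about z",
               "-1 0 0 0", "0 -1 0 0", "0 0 1 0", "0 0 0 1",
               "", "# translation by 100 A",
               "1 0 0 100", "0 1 0 0", "0 0 1 0", "0 0 0 1"), f)
  ops <- read_operators(f)
  expect_length(ops, 2)
  expect_equal(ops[[1]]$rotation, diag(c(-1, -1, 1)))
  expect_equal(ops[[2]]$translation, c(100, 0, 0))
  unlink(f)
})

test_that("crystal neighbours keep contacting images and drop the rest", {
  dimer <- fix_dimer()
  half <- dimer
  half$atoms <- half$atoms[half$atoms$chain == "A", , drop = FALSE]
  ops <- list(
    symmetry_operator(diag(3), label = "ident"),
    symmetry_operator(diag(3), c(100, 0, 0), label = "far"),
    symmetry_operator(capriqa:::rotation_about_axis(c(0, 0, 1), 180),
                      label = "c2")
  )
  aug <- generate_crystal_neighbors(half, ops)
  imgs <- attr(aug, "images")
  expect_equal(imgs$operator, "c2")  # identity and far images discarded
  expect_equal(structure_chains(aug), c("A", "A~c2"))
  # the symmetry-generated dimer buries the same area as the direct one
  a1 <- interface_area(chain_atoms(aug, "A"), chain_atoms(aug, "A~c2"),
                       sphere_points = 480)
  a2 <- interface_area(chain_atoms(dimer, "A"), chain_atoms(dimer, "B"),
                       sphere_points = 480)
  expect_equal(a1$interface_area, a2$interface_area, tolerance = 1e-6)
})

test_that("interface enumeration ranks by area and merges symmetry copies", {
  mono <- fix_subunit(n = 10)
  expect_equal(nrow(enumerate_interfaces(mono)), 0L)
  tet <- fix_tetramer()
  iff <- enumerate_interfaces(tet, min_area = 2, config = fix_config())
  expect_equal(nrow(iff), 2L)  # intra-dimer and inter-dimer classes
  expect_true(all(diff(iff$area) <= 0))
  expect_equal(iff$n_equivalent, c(2L, 2L))
  expect_equal(iff$id, c(1L, 2L))
})

test_that("two far-apart congruent dimers merge into one interface class", {
  d <- fix_dimer(n = 12)
  shifted <- d$atoms
  shifted$x <- shifted$x + 200
  shifted$chain <- ifelse(shifted$chain == "A", "C", "D")
  two <- d
  two$atoms <- rbind(d$atoms, shifted)
  iff <- enumerate_interfaces(two, min_area = 2, config = fix_config())
  expect_equal(nrow(iff), 1L)
  expect_equal(iff$n_equivalent, 2L)
})

test_that("enumeration is invariant under a global rigid motion", {
  tet <- fix_tetramer()
  tf <- rigid_transform(capriqa:::rotation_about_axis(c(2, 1, 5), 71),
                        c(13, -4, 6))
  moved <- tet
  xyz <- apply_transform(tf, as.matrix(tet$atoms[, c("x", "y", "z")]))
  moved$atoms$x <- xyz[, 1]; moved$atoms$y <- xyz[, 2]
  moved$atoms$z <- xyz[, 3]
  i1 <- enumerate_interfaces(tet, min_area = 2, config = fix_config())
  i2 <- enumerate_interfaces(moved, min_area = 2, config = fix_config())
  expect_equal(i2$area, i1$area, tolerance = 1e-6)
  expect_equal(i2$n_equivalent, i1$n_equivalent)
})

test_that("chain relabelling of a symmetric model leaves metrics unchanged", {
  d <- fix_dimer()
  iff <- enumerate_interfaces(d, min_area = 2, config = fix_config())
  base <- assess_model(d, d, interfaces = iff, config = fix_config())
  swapped <- d
  swapped$atoms$chain <- ifelse(d$atoms$chain == "A", "B", "A")
  swapped$atoms <- swapped$atoms[order(match(swapped$atoms$chain,
                                             c("A", "B"))), ]
  rel <- assess_model(swapped, d, interfaces = iff, config = fix_config())
  expect_equal(rel$best_metrics$f_nat, base$best_metrics$f_nat)
  expect_equal(rel$best_metrics$l_rms, base$best_metrics$l_rms,
               tolerance = 1e-8)
  expect_equal(rel$best_metrics$i_rms, base$best_metrics$i_rms,
               tolerance = 1e-8)
  expect_equal(as.character(rel$best_quality),
               as.character(base$best_quality))
})

test_that("for a C2 target both role assignments give identical best metrics", {
  d <- fix_dimer()
  dec <- make_decoys(d, list(decoy_spec(translation = c(1, 0, 2))))
  corr <- map_common_residues(dec$models[[1]], d)
  m1 <- ligand_rms(dec$models[[1]], d, corr, "A", "B")
  m2 <- ligand_rms(dec$models[[1]], d, corr, "B", "A")
  expect_equal(m1$l_rms, m2$l_rms, tolerance = 1e-6)
})

test_that("tetramer permutation matching finds the optimum over all 4! maps", {
  tet <- fix_tetramer(n = 20)
  iff <- enumerate_interfaces(tet, min_area = 2, config = fix_config())
  # scramble chain labels of a perfect model: A->C->B->D->A
  perm <- c(A = "C", B = "D", C = "B", D = "A")
  scr <- tet
  scr$atoms$chain <- unname(perm[scr$atoms$chain])
  scr$atoms <- scr$atoms[order(match(scr$atoms$chain, names(perm))), ]
  rec <- assess_model(scr, tet, interfaces = iff, config = fix_config())
  expect_true(all(rec$per_interface$quality == "high"))
  expect_true(all(rec$per_interface$l_rms < 1e-6))
  # exhaustive oracle: directly try all 24 chain bijections
  cfg <- fix_config()
  best_i <- Inf
  for (p in list(c("A","B","C","D"), c("A","B","D","C"), c("A","C","B","D"),
                 c("A","C","D","B"), c("A","D","B","C"), c("A","D","C","B"),
                 c("B","A","C","D"), c("B","A","D","C"), c("B","C","A","D"),
                 c("B","C","D","A"), c("B","D","A","C"), c("B","D","C","A"),
                 c("C","A","B","D"), c("C","A","D","B"), c("C","B","A","D"),
                 c("C","B","D","A"), c("C","D","A","B"), c("C","D","B","A"),
                 c("D","A","B","C"), c("D","A","C","B"), c("D","B","A","C"),
                 c("D","B","C","A"), c("D","C","A","B"), c("D","C","B","A"))) {
    names(p) <- c("A", "B", "C", "D")  # model chain -> target chain
    inv <- setNames(names(p), p)
    m <- try(capri_metrics(
      scr, tet, receptor_chains = iff$chain_a[1],
      ligand_chains = iff$chain_b[1],
      corr = map_common_residues(scr, tet, data.frame(
        model = c(inv[[iff$chain_a[1]]], inv[[iff$chain_b[1]]]),
        target = c(iff$chain_a[1], iff$chain_b[1]))),
      config = cfg), silent = TRUE)
    if (!inherits(m, "try-error")) best_i <- min(best_i, m$i_rms)
  }
  expect_equal(rec$per_interface$i_rms[1], best_i, tolerance = 1e-8)
})

test_that("a model correct on one interface only is scored per interface", {
  tet <- fix_tetramer(n = 20)
  iff <- enumerate_interfaces(tet, min_area = 2, config = fix_config())
  # break the inter-dimer interface: move the CD dimer far away, keeping
  # the AB dimer intact
  broken <- tet
  sel <- broken$atoms$chain %in% c("C", "D")
  broken$atoms$y[sel] <- broken$atoms$y[sel] - 60
  rec <- assess_model(broken, tet, interfaces = iff, config = fix_config())
  pi <- rec$per_interface
  intra <- which(pi$interface_id == 1L)  # larger, intra-dimer interface
  expect_equal(pi$quality[intra], "high")
  expect_true(pi$quality[pi$interface_id == 2L] == "incorrect")
  expect_equal(rec$best_interface, 1L)
})

test_that("simultaneous capture requires one mapping for all interfaces", {
  tet <- fix_tetramer(n = 20)
  iff <- enumerate_interfaces(tet, min_area = 2, config = fix_config())
  ids <- iff$id
  perfect <- assess_model(tet, tet, interfaces = iff, config = fix_config())
  expect_true(simultaneous_capture(perfect, ids, "high"))
  expect_error(simultaneous_capture(perfect, c(ids, 99L)), "not assessed")
  # single-interface model: only a dimer pair is right
  broken <- tet
  sel <- broken$atoms$chain %in% c("C", "D")
  broken$atoms$y[sel] <- broken$atoms$y[sel] - 60
  rec <- assess_model(broken, tet, interfaces = iff, config = fix_config())
  expect_false(simultaneous_capture(rec, ids, "acceptable"))
})

test_that("a model whose interfaces are individually right but mutually
           incompatible fails the simultaneous check", {
  tet <- fix_tetramer(n = 20)
  iff <- enumerate_interfaces(tet, min_area = 2, config = fix_config())
  # model made of two disjoint sub-assemblies: chains A,B copy the target
  # intra-dimer pair; chains C,D copy the target inter-dimer pair (A:C),
  # shifted far away. Each interface is reproduced by SOME pair, but no
  # single whole-model bijection captures both.
  ta <- chain_atoms(tet, iff$chain_a[1]); tb <- chain_atoms(tet, iff$chain_b[1])
  tc <- chain_atoms(tet, iff$chain_a[2]); td <- chain_atoms(tet, iff$chain_b[2])
  ta$chain <- "A"; tb$chain <- "B"
  tc$chain <- "C"; td$chain <- "D"
  tc$x <- tc$x + 200; td$x <- td$x + 200
  frank <- tet
  frank$atoms <- rbind(ta, tb, tc, td)
  frank$id <- "frankenstein"
  rec <- assess_model(frank, tet, interfaces = iff, config = fix_config())
  pi <- rec$per_interface
  # each interface is predicted somewhere in the model...
  expect_true(all(pi$quality == "high"))
  # ...but no single chain assignment captures both at once
  expect_false(simultaneous_capture(rec, iff$id, "acceptable"))
})
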