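test_that("confidence kind detection follows the stated conventions", {
  expect_equal(detect_confidence_kind(c(0.93, 0.41, 0.88)), "plddt1")
  expect_equal(detect_confidence_kind(c(88, 42, 91.5)), "plddt100")
  expect_equal(detect_confidence_kind(c(0.8, 1.4, 3.9)), "rmsd_angstrom")
  expect_equal(detect_confidence_kind(c(0.8, 1.4, 3.9),
                                      declared = "rmsd_angstrom"),
               "rmsd_angstrom")
  # values above 100 cannot be pLDDT
  expect_equal(detect_confidence_kind(c(30, 150, 80)), "bfactor_already")
  # mostly tiny values with a rare spike above 20: not pLDDT, not rmsd
  expect_equal(detect_confidence_kind(c(rep(2, 99), 30)), "bfactor_already")
  expect_error(detect_confidence_kind(c(5, -1)), "invalid confidence values")
})

test_that("pLDDT to r.m.s.d. conversion matches its closed form", {
  expect_equal(plddt_to_rmsd(0.70), 1.5)
  expect_equal(plddt_to_rmsd(1.00), 1.5 * exp(-1.2), tolerance = 1e-12)
  expect_equal(plddt_to_rmsd(0.00), 20)            # capped (uncapped 24.66)
  expect_gt(1.5 * exp(4 * 0.7), 20)
  expect_error(plddt_to_rmsd(1.2), "pLDDT out of range")
  expect_error(plddt_to_rmsd(-0.1), "pLDDT out of range")
  # strictly decreasing wherever uncapped
  p <- seq(0, 1, by = 0.001)
  r <- plddt_to_rmsd(p)
  unc <- r < 20
  expect_true(all(diff(r[unc]) < 0))
})

test_that("r.m.s.d. to B factor conversion and its inverse agree", {
  expect_equal(rmsd_to_bfactor(0), 0)
  expect_equal(rmsd_to_bfactor(1.5), (8 * pi^2 / 3) * 2.25, tolerance = 1e-12)
  expect_equal(rmsd_to_bfactor(0.4518), (8 * pi^2 / 3) * 0.4518^2,
               tolerance = 1e-12)
  expect_error(rmsd_to_bfactor(-1), "invalid rmsd")
  r <- seq(0, 20, by = 0.05)
  expect_equal(bfactor_to_rmsd(rmsd_to_bfactor(r)), r, tolerance = 1e-9)
})

test_that("convert_to_bfactors rewrites every atom with the residue-level B", {
  atoms <- tibble::tibble(
    atom = c("N", "CA", "C", "CA"), resid = "ALA", chain = "A",
    resno = c(1, 1, 1, 2), x = c(0, 1, 2, 5), y = 0, z = 0, occ = 1,
    b = c(70, 70, 70, 50)
  )
  m <- predicted_model(atoms)
  conv <- convert_to_bfactors(m)
  b70 <- rmsd_to_bfactor(plddt_to_rmsd(0.70))
  expect_equal(conv$b[1:3], rep(b70, 3), tolerance = 1e-12)
  expect_equal(b70, 59.21762, tolerance = 1e-6)
  # higher confidence, lower B
  m2 <- line_model(2, b = c(90, 50))
  c2 <- convert_to_bfactors(m2)
  expect_lt(c2$b[1], c2$b[2])
  # declared genuine B factors pass through untouched
  m3 <- line_model(3, b = c(20, 150, 40))
  expect_identical(convert_to_bfactors(m3)$b, m3$b)
  # misaligned profile
  prof <- confidence_profile(line_model(5))
  expect_error(convert_to_bfactors(m2, prof), "profile/model length mismatch")
})

test_that("pruning keeps exactly the residues at or above the cutoff", {
  m <- line_model(4, b = c(95, 69.9, 70, 30))
  pruned <- prune_low_confidence(m)
  expect_equal(residues(pruned)$resno, c(1L, 3L))
  # threshold 0 keeps everything; pruning is idempotent
  expect_equal(nrow(prune_low_confidence(m, threshold = 0)), nrow(m))
  prof <- confidence_profile(m)
  once <- prune_low_confidence(m, prof)
  prof_once <- confidence_profile(once)
  expect_identical(prune_low_confidence(once, prof_once)$resno, once$resno)
  # fractional-scale profiles rescale the threshold
  mf <- line_model(3, b = c(0.95, 0.5, 0.71))
  expect_equal(residues(prune_low_confidence(mf))$resno, c(1L, 3L))
})

test_that("r.m.s.d. profiles need an explicit Angstrom cutoff", {
  m <- line_model(3, b = c(0.9, 2.5, 6))
  expect_error(prune_low_confidence(m), "threshold kind mismatch")
  kept <- prune_low_confidence(m, rmsd_threshold = 3)
  expect_equal(residues(kept)$resno, c(1L, 2L))
})

test_that("pruning matches a brute-force filter on random profiles", {
  for (seed in 1:20) {
    withr::with_seed(seed, {
      n <- sample(5:60, 1)
      b <- round(runif(n, 20, 100), 2)
      thr <- sample(c(50, 70, 90), 1)
      m <- line_model(n, b = b)
      got <- residues(prune_low_confidence(m, threshold = thr))$resno
      expect_identical(got, which(b >= thr))
    })
  }
})

test_that("short disconnected segments are removed", {
  # numbering gaps split 97 residues into segments of 40 / 2 / 55
  m <- line_model(97, resno = c(1:40, 101:102, 201:255))
  cleaned <- remove_short_segments(m, min_len = 3)
  expect_equal(nrow(residues(cleaned)), 95)
  expect_false(any(residues(cleaned)$resno %in% 101:102))
  # min_len 1 is the identity
  expect_equal(nrow(remove_short_segments(m, min_len = 1)), nrow(m))
  # a large spatial gap forces a break even with continuous numbering
  xyz <- cbind(3.8 * 1:10, 0, 0)
  xyz[1:2, 1] <- xyz[1:2, 1] - 8            # 8 A CA gap after residue 2
  m2 <- ca_model(xyz, b = 90)
  expect_equal(residues(remove_short_segments(m2))$resno, 3:10)
  # re-segmenting the output is a fixed point
  out <- remove_short_segments(m, min_len = 5)
  expect_identical(remove_short_segments(out, min_len = 5)$resno, out$resno)
})

test_that("trim_to_target keeps the union of inclusive ranges", {
  m <- line_model(6, resno = 9:14)
  kept <- trim_to_target(m, tibble::tibble(chain = "A", start = 10, end = 12))
  expect_equal(residues(kept)$resno, 10:12)
  expect_equal(nrow(trim_to_target(m, tibble::tibble(
    chain = character(), start = integer(), end = integer()))), 0)
  both <- trim_to_target(m, tibble::tibble(chain = "A", start = c(9, 11),
                                           end = c(12, 14)))
  expect_equal(residues(both)$resno, 9:14)
  expect_error(trim_to_target(m, tibble::tibble(chain = "B", start = 1,
                                                end = 2)), "unknown chain")
})

test_that("alignment to a target sequence yields the aligned ranges", {
  seq20 <- c("ALA", "CYS", "ASP", "GLU", "PHE", "GLY", "HIS", "ILE", "LYS",
             "LEU", "MET", "ASN", "PRO", "GLN", "ARG", "SER", "THR", "VAL",
             "TRP", "TYR")
  m <- ca_model(cbind(3.8 * 1:20, 0, 0), b = 90, resid = seq20)
  # target is positions 5..16 of the model sequence
  target <- "FGHIKLMNPQRS"
  ranges <- align_to_target(m, target)
  expect_equal(nrow(ranges), 1)
  expect_equal(ranges$start, 5)
  expect_equal(ranges$end, 16)
  trimmed <- trim_to_target(m, ranges)
  expect_equal(residues(trimmed)$resno, 5:16)
  # FASTA path input
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">target", target), fa)
  expect_equal(align_to_target(m, fa), ranges)
})
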