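test_that("worked examples of the individual statistics are exact", {
  # distinct-haplotype counting: rows {00,00,01,11}, n = 4, L = 10
  aln <- hap_alignment(rbind(c(0, 0), c(0, 0), c(0, 1), c(1, 1)), c(2, 7), 10)
  expect_equal(stat_haps(aln), 3 / 40)
  # all rows identical -> one haplotype
  mono <- hap_alignment(matrix(0L, 4, 0), numeric(0), 100)
  expect_equal(stat_haps(mono), 1 / 400)
  expect_equal(stat_wath(mono), 0)
  expect_equal(unname(stat_pairwise(mono)), c(0, 0))

  # Watterson: n = 4, S = 3, L = 100, a_4 = 11/6
  w <- hap_alignment(rbind(c(0, 0, 0), c(1, 1, 1), c(0, 1, 0), c(1, 0, 1)),
                     c(1, 2, 3), 100)
  expect_equal(stat_wath(w), 3 / (11 / 6 * 100))
  # n = 2: a_2 = 1
  w2 <- hap_alignment(rbind(rep(0, 5), rep(1, 5)), 0:4, 1000)
  expect_equal(stat_wath(w2), 0.005)

  # pairwise distances {1,2,3}/10 -> mean 0.2, population variance 1/150
  p3 <- hap_alignment(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 1)),
                      c(0, 4, 8), 10)
  pw <- stat_pairwise(p3)
  expect_equal(pw[["apwd"]], 0.2)
  expect_equal(pw[["vapw"]], 0.006666667, tolerance = 1e-6)
  # single pair differing at 1 of 100 bp
  p2 <- hap_alignment(rbind(0L, 1L), 50, 100)
  expect_equal(unname(stat_pairwise(p2)), c(0.01, 0))

  # heterozygosity: n = 2 singleton site -> 1; n = 4 counts (2,2) -> 2/3*...
  expect_equal(stat_hahe(p2), 1)
  h4 <- hap_alignment(rbind(c(0, 1), c(0, 1), c(1, 0), c(1, 0)), c(1, 5), 10)
  expect_equal(stat_hahe(h4), 4 / 3 * 0.5)

  # maxchi: mismatch vector (1,1,1,1,0,0,0,0) at split 4 gives chi^2 = 8
  m <- hap_alignment(rbind(rep(0, 8), c(1, 1, 1, 1, 0, 0, 0, 0),
                           c(0, 0, 0, 0, 1, 1, 1, 1)), 0:7, 20)
  expect_equal(stat_maxchi(m), 8)
  # identical pair only -> 0 mismatches -> 0
  same <- hap_alignment(rbind(c(0, 1), c(0, 1), c(1, 0)), c(0, 1), 10)
  expect_gte(stat_maxchi(same), 0)

  # NSS: tree-like data (nested, no 4-gamete violation) -> 1
  tree <- hap_alignment(rbind(c(1, 1), c(1, 0), c(0, 0), c(0, 0)),
                        c(0, 1), 10)
  expect_equal(stat_nss(tree), 1)
  # every adjacent pair incompatible -> 0
  bad <- hap_alignment(rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1)),
                       c(0, 1), 10)
  expect_equal(stat_nss(bad), 0)
})

test_that("Tajima's D has the expected sign behaviour", {
  # excess singletons -> negative D
  m <- rbind(diag(1L, 8), matrix(0L, 2, 8))
  alnS <- hap_alignment(m, 0:7, 100)
  expect_lt(stat_tajd(alnS), 0)
  expect_equal(stat_tajd(alnS), oracle_tajd(alnS$mat), tolerance = 1e-12)
})

test_that("all statistics match naive brute-force oracles on random alignments", {
  set.seed(2024)
  for (rep in 1:500) {
    n <- sample(4:8, 1)
    S <- sample(2:12, 1)
    aln <- random_alignment(n, S)
    expect_equal(stat_haps(aln), oracle_haps(aln$mat, aln$length_bp),
                 tolerance = 1e-10)
    expect_equal(stat_wath(aln), oracle_wath(aln$mat, aln$length_bp),
                 tolerance = 1e-10)
    expect_equal(unname(stat_pairwise(aln)),
                 unname(oracle_pairwise(aln$mat, aln$length_bp)),
                 tolerance = 1e-10)
    expect_equal(stat_hahe(aln), oracle_hahe(aln$mat), tolerance = 1e-10)
    expect_equal(stat_nss(aln), oracle_nss(aln$mat), tolerance = 1e-10)
    expect_equal(stat_maxchi(aln), oracle_maxchi(aln$mat), tolerance = 1e-10)
    expect_equal(stat_tajd(aln), oracle_tajd(aln$mat), tolerance = 1e-10)
  }
})

test_that("statistics are invariant to row order and allele relabeling", {
  set.seed(99)
  for (rep in 1:25) {
    aln <- random_alignment(6, 8)
    perm <- hap_alignment(aln$mat[sample(6), ], aln$positions, aln$length_bp)
    flip_cols <- sample(8, 3)
    fmat <- aln$mat; fmat[, flip_cols] <- 1L - fmat[, flip_cols]
    flip <- hap_alignment(fmat, aln$positions, aln$length_bp)
    for (f in list(stat_haps, stat_wath, stat_hahe, stat_nss, stat_maxchi,
                   function(a) stat_pairwise(a)[["apwd"]],
                   function(a) stat_pairwise(a)[["vapw"]])) {
      expect_equal(f(perm), f(aln), tolerance = 1e-12)
      expect_equal(f(flip), f(aln), tolerance = 1e-12)
    }
  }
})

test_that("per-bp statistics scale as 1/L for fixed SNP content", {
  set.seed(7)
  aln1 <- random_alignment(6, 10, L = 100)
  aln2 <- hap_alignment(aln1$mat, aln1$positions, 500)
  expect_equal(stat_wath(aln2), stat_wath(aln1) / 5)
  expect_equal(stat_pairwise(aln2)[["apwd"]], stat_pairwise(aln1)[["apwd"]] / 5)
  expect_equal(stat_haps(aln2), stat_haps(aln1) / 5)
})

test_that("summarize_segment composes the statistics and flags sparse segments", {
  aln <- random_alignment(6, 8)
  sv <- summarize_segment(aln, include_tajd = TRUE)
  expect_equal(sv$haps, stat_haps(aln))
  expect_equal(sv$wath, stat_wath(aln))
  expect_equal(sv$maxchi, stat_maxchi(aln))
  expect_equal(sv$tajd, stat_tajd(aln))
  expect_false(sv$impute)
  expect_true(sv$nss >= 0 && sv$nss <= 1)

  empty <- hap_alignment(matrix(0L, 4, 0), numeric(0), 1000)
  sv0 <- summarize_segment(empty)
  expect_true(sv0$impute)
  expect_equal(sv0$wath, 0)
  expect_equal(sv0$apwd, 0)
  expect_true(is.na(sv0$tajd))

  sv_no_tajd <- summarize_segment(aln, include_tajd = FALSE)
  expect_true(is.na(sv_no_tajd$tajd))
})
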