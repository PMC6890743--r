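test_that("sequences without allowed pairs fold to the empty structure", {
  f <- fold_mfe("AAAAAAAAAA")
  expect_equal(f$dot_bracket, "..........")
  expect_equal(f$mfe, 0)
  # too short for any pair under the loop constraint
  f2 <- fold_mfe("GCA")
  expect_equal(f2$mfe, 0)
  expect_equal(f2$dot_bracket, "...")
  expect_error(fold_mfe("ACGX"), "characters")
})

test_that("MFE folding equals the exhaustive enumeration minimum", {
  m <- energy_model()
  set.seed(101)
  for (i in 1:60) {
    s <- random_rna_str(sample(5:16, 1))
    en <- enumerate_structures(s, m)
    f <- fold_mfe(s, m)
    expect_equal(f$mfe, min(en$energies), tolerance = 1e-12, info = s)
    # the traced structure carries exactly its claimed energy
    expect_equal(lncmir:::structure_energy(s, f$partner, m), f$mfe,
                 tolerance = 1e-12, info = s)
  }
})

test_that("structure enumeration agrees with the independent recursion count", {
  m <- energy_model()
  expect_equal(length(enumerate_structures("AAAA", m)$energies), 1)
  expect_true("((((...))))" %in%
                enumerate_structures("GGGGAAACCCC", m)$dot_brackets)
  set.seed(7)
  for (i in 1:30) {
    s <- random_rna_str(sample(6:12, 1))
    expect_equal(length(enumerate_structures(s, m)$energies),
                 count_structures(s, m), info = s)
  }
  expect_error(enumerate_structures(random_rna_str(40), m), "cap")
})

test_that("partition function matches exhaustive Boltzmann sums", {
  m <- energy_model()
  pf0 <- partition_function("AAAA", m)
  expect_equal(pf0$Z, 1)
  expect_true(all(pf0$p == 0))
  expect_equal(unname(pf0$NQ), 0)
  expect_equal(unname(pf0$ND), 0)
  set.seed(202)
  for (i in 1:40) {
    L <- sample(6:14, 1)
    s <- random_rna_str(L)
    en <- enumerate_structures(s, m)
    w <- exp(-en$energies / m$kT)
    Z <- sum(w)
    pm <- matrix(0, L, L)
    for (k in seq_along(en$partners)) {
      p <- en$partners[[k]]
      idx <- which(!is.na(p) & p > seq_len(L))
      for (ii in idx) pm[ii, p[ii]] <- pm[ii, p[ii]] + w[k]
    }
    pm <- pm / Z
    pf <- partition_function(s, m)
    expect_lt(abs(pf$Z - Z) / Z, 1e-9)
    expect_lt(max(abs(pm[upper.tri(pm)] - pf$p[upper.tri(pf$p)])), 1e-9)
    # ensemble indices recomputed from oracle probabilities agree
    st <- lncmir:::ensemble_stats_from_p(pm)
    expect_equal(unname(pf$NQ), unname(st["NQ"]), tolerance = 1e-9)
    expect_equal(unname(pf$ND), unname(st["ND"]), tolerance = 1e-9)
    # row sums of pair probabilities never exceed 1
    expect_true(all(rowSums(pf$p) <= 1 + 1e-9))
    expect_gte(pf$Z, 1)
  }
})

test_that("ensemble indices are invariant under sequence reversal", {
  # reversal maps pair (i,j) to (L+1-j, L+1-i), sending AU<->UA, GC<->CG,
  # GU<->UG; the stack table is symmetric under this duplex reversal, so
  # the Boltzmann ensemble maps onto itself. (Reverse *complement* is not
  # a symmetry: G:U wobbles are not closed under complementation.)
  m <- energy_model()
  set.seed(33)
  for (i in 1:10) {
    s <- random_rna_str(sample(10:20, 1))
    rc <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    a <- partition_function(s, m)
    b <- partition_function(rc, m)
    expect_equal(unname(a$NQ), unname(b$NQ), tolerance = 1e-9, info = s)
    expect_equal(unname(a$ND), unname(b$ND), tolerance = 1e-9, info = s)
    expect_equal(a$Z, b$Z, tolerance = 1e-9, info = s)
  }
})

test_that("hairpin descriptors follow their defining arithmetic", {
  st <- fold_mfe("GGGGGAAAACCCCC")
  d <- hairpin_descriptors(st)
  expect_equal(d$AMFE, abs(st$mfe) / 14 * 100)
  expect_equal(d$MFEI, d$AMFE / d$gc_pct)
  expect_equal(d$Npb, nrow(st$pairs) / 14)
  # hand-built case: |MFE| 40, L 100, GC 50% -> AMFE 40, MFEI 0.8
  fake <- structure(list(sequence = paste(rep(c("G", "A"), 50), collapse = ""),
                         dot_bracket = strrep(".", 100),
                         partner = rep(NA_integer_, 100),
                         pairs = cbind(i = integer(0), j = integer(0)),
                         mfe = -40), class = "rna_structure")
  fd <- hairpin_descriptors(fake)
  expect_equal(fd$AMFE, 40)
  expect_equal(fd$MFEI, 0.8)
  # zero-GC precursor: MFEI undefined, rejection flag raised
  au <- fold_mfe(strrep("AU", 10))
  expect_true(hairpin_descriptors(au)$gc_zero)
})

test_that("MFEI is roughly length-invariant for a doubled perfect stem", {
  stem <- function(n) {
    paste0(strrep("GC", n), "AAAA", revcomp_rna(strrep("GC", n)))
  }
  d1 <- hairpin_descriptors(fold_mfe(stem(10)))
  d2 <- hairpin_descriptors(fold_mfe(stem(20)))
  expect_lt(abs(d1$MFEI - d2$MFEI) / d1$MFEI, 0.1)
})

test_that("duplex energy of a perfect complement is the stack-term sum", {
  m <- energy_model()
  set.seed(55)
  s <- random_rna_str(20)
  dx <- duplex_score(s, revcomp_rna(s), m)
  ch <- strsplit(s, "")[[1]]
  pt <- function(a) match(paste0(a, chartr("ACGU", "UGCA", a)),
                          c("AU", "UA", "GC", "CG", "GU", "UG"))
  manual <- sum(vapply(1:19, function(k) m$stack[pt(ch[k]), pt(ch[k + 1])],
                       numeric(1)))
  expect_equal(dx$energy, manual)
  expect_equal(nrow(dx$alignment), 20)
})

test_that("duplex scoring matches the brute-force alignment search", {
  m <- energy_model()
  expect_equal(duplex_score(strrep("A", 8), strrep("C", 8), m)$energy, 0)
  set.seed(66)
  for (i in 1:20) {
    a <- random_rna_str(sample(6:9, 1))
    b <- random_rna_str(sample(6:9, 1))
    expect_equal(duplex_score(a, b, m)$energy,
                 lncmir:::duplex_bruteforce(a, b, m),
                 tolerance = 1e-12, info = paste(a, b))
  }
})

test_that("a central mismatch destabilizes the duplex", {
  m <- energy_model()
  set.seed(77)
  for (i in 1:5) {
    s <- random_rna_str(20)
    rc <- revcomp_rna(s)
    perfect <- duplex_score(s, rc, m)$energy
    ch <- strsplit(rc, "")[[1]]
    ch[10] <- lncmir:::complement_rna(ch[10]) # breaks the pair at center
    mut <- duplex_score(s, paste(ch, collapse = ""), m)$energy
    expect_gt(mut, perfect)
  }
})

test_that("dot-bracket parsing round-trips and rejects imbalance", {
  p <- dot_bracket_partners("((..))")
  expect_equal(p, c(6L, 5L, NA, NA, 2L, 1L))
  expect_error(dot_bracket_partners("(()"), "unbalanced")
  expect_error(dot_bracket_partners("())"), "unbalanced")
})
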