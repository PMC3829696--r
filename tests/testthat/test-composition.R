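test_that("scan_sequence computes gc and o/e ratios from direct counts", {
  p <- scan_sequence(nuc_sequence("ex", "ACGT"))
  expect_equal(p$gc, 0.5)
  expect_equal(sum(p$counts), 3)           # 3 overlapping windows
  expect_equal(unname(p$counts["CG"]), 1)
  expect_equal(p$ratios[["CG"]], (1 / 3) / (0.25 * 0.25))
})

test_that("degenerate single-base composition is handled per mode", {
  p <- scan_sequence(strrep("A", 50), mode = "rna")
  expect_equal(p$gc, 0)
  expect_equal(p$ratios[["AA"]], 1)        # p_A = 1 under RNA convention
  expect_true(all(is.na(p$ratios[c("CC", "CG", "GC", "AC", "CA")])))
})

test_that("too-short or fully ambiguous input is rejected", {
  expect_error(scan_sequence("A", mode = "dna"), "fewer than 2")
  expect_error(scan_sequence("NNNNN", mode = "dna"), "fewer than 2")
})

test_that("ambiguous bases break the window chain", {
  p <- scan_sequence("ACGTNACGT")
  expect_equal(sum(p$counts), 6)           # 8 windows, 2 span the N
  expect_equal(unname(p$counts["CG"]), 2)
  expect_equal(p$length, 8L)
})

test_that("window counts sum to scored windows across random inputs", {
  set.seed(101)
  for (rep in 1:5) {
    n <- sample(500:2000, 1)
    s <- random_iid_sequence(n, p = c(0.3, 0.2, 0.2, 0.3))
    # inject ambiguity
    idx <- sample(n, 20)
    substr_vec <- strsplit(s, "")[[1]]
    substr_vec[idx] <- "N"
    s2 <- paste(substr_vec, collapse = "")
    p <- scan_sequence(s2)
    runs <- nchar(strsplit(gsub("N+", " ", s2), " ")[[1]])
    expect_equal(sum(p$counts), sum(pmax(runs - 1, 0)))
  }
})

test_that("an i.i.d. sequence has all o/e ratios near 1", {
  set.seed(1)
  s <- random_iid_sequence(10000)
  p <- scan_sequence(s, mode = "rna")
  W <- sum(p$counts)
  se_ratio <- sqrt((1 / 16) * (15 / 16) / W) / (1 / 16)
  expect_true(all(abs(p$ratios - 1) < 3 * se_ratio))
  # non-uniform composition, DNA convention with A=T, C=G
  set.seed(2)
  s2 <- random_iid_sequence(10000, p = c(0.35, 0.15, 0.15, 0.35))
  p2 <- scan_sequence(s2, mode = "dna")
  for (dn in DINUC16) {
    e <- prod(ifelse(strsplit(dn, "")[[1]] %in% c("C", "G"),
                     p2$gc / 2, (1 - p2$gc) / 2))
    se <- sqrt(e * (1 - e) / W) / e
    expect_lt(abs(p2$ratios[[dn]] - 1), 3 * se)
  }
})

test_that("double-stranded scanning is exactly strand-symmetric", {
  set.seed(3)
  s <- random_iid_sequence(3000, p = c(0.4, 0.2, 0.1, 0.3))
  p <- scan_double_stranded(s)
  rc_name <- function(dn) {
    b <- strsplit(dn, "")[[1]]
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste0(comp[b[2]], comp[b[1]])
  }
  for (dn in DINUC16)
    expect_identical(p$ratios[[dn]], p$ratios[[rc_name(dn)]])
})

test_that("fragment_sequence applies the half-length remainder rule", {
  long <- nuc_sequence("chr", random_iid_sequence(130000))
  frags <- fragment_sequence(long, 50000)
  expect_length(frags, 3)                  # 30,000 remainder kept
  expect_equal(nchar(frags[[3]]$bases), 30000)

  mid <- nuc_sequence("chr", random_iid_sequence(120000))
  frags2 <- fragment_sequence(mid, 50000)
  expect_length(frags2, 2)                 # 20,000 remainder discarded
  expect_true(all(vapply(frags2, function(f) nchar(f$bases), 1) == 50000))

  exact <- nuc_sequence("one", random_iid_sequence(50000))
  expect_length(fragment_sequence(exact, 50000), 1)

  expect_error(fragment_sequence(nuc_sequence("s", random_iid_sequence(99)),
                                 100), "shorter")
  expect_error(fragment_sequence(exact, 50), "at least 100")
})

test_that("quadratic baseline recovers exact coefficients and zero RMS", {
  set.seed(4)
  coefs <- matrix(runif(48, -1, 1), 16, 3)
  gc <- seq(0.3, 0.7, length.out = 20)
  profiles <- lapply(seq_along(gc), function(n) {
    r <- coefs[, 1] + coefs[, 2] * gc[n] + coefs[, 3] * gc[n]^2
    names(r) <- DINUC16
    dinucleotide_profile(gc = gc[n], ratios = r, id = paste0("p", n))
  })
  fit <- fit_quadratic_baseline(profiles)
  expect_lt(max(abs(fit$coefficients - coefs)), 1e-10)
  expect_lt(fit$baseline_rms, 1e-12)
})

test_that("quadratic baseline RMS matches the injected noise level", {
  set.seed(5)
  gc <- runif(500, 0.25, 0.75)
  profiles <- lapply(seq_along(gc), function(n) {
    r <- 1 + 0.5 * gc[n] - 0.4 * gc[n]^2 + rnorm(16, sd = 0.05)
    names(r) <- DINUC16
    dinucleotide_profile(gc = gc[n], ratios = r, id = paste0("p", n))
  })
  fit <- fit_quadratic_baseline(profiles)
  expect_gt(fit$baseline_rms, 0.04)
  expect_lt(fit$baseline_rms, 0.06)
})

test_that("quadratic baseline needs 3 distinct G+C values", {
  r <- stats::setNames(rep(1, 16), DINUC16)
  profiles <- list(dinucleotide_profile(0.4, r), dinucleotide_profile(0.4, r),
                   dinucleotide_profile(0.6, r))
  expect_error(fit_quadratic_baseline(profiles), "distinct")
})

test_that("sampling-error fit recovers noiseless parameters within 1%", {
  L <- c(500, 1000, 2000, 5000, 10000, 50000, 100000, 400000)
  y <- 2.2 / L^0.42 + 0.0095
  fit <- fit_sampling_error(L, y)
  expect_lt(abs(fit$a - 2.2) / 2.2, 0.01)
  expect_lt(abs(fit$b - 0.42) / 0.42, 0.01)
  expect_lt(abs(fit$c - 0.0095) / 0.0095, 0.01)
})

test_that("constant RMS collapses to a pure intercept", {
  fit <- fit_sampling_error(c(1000, 2000, 4000, 8000), rep(0.031, 4))
  expect_equal(fit$a, 0)
  expect_equal(fit$c, 0.031)
})

test_that("sampling-error fit preconditions are enforced", {
  expect_error(fit_sampling_error(c(100, 200, 300), c(0.1, 0.08, 0.07)),
               "at least 4")
  expect_error(fit_sampling_error(c(-1, 200, 300, 400), rep(0.1, 4)),
               "positive")
})

test_that("evaluate_sampling_error follows a / L^b + c", {
  fit <- structure(list(a = 2.2, b = 0.42, c = 0.0095),
                   class = "sampling_error_fit")
  expect_equal(evaluate_sampling_error(fit, 1), 2.2095)
  expect_equal(evaluate_sampling_error(fit, 1e20), 0.0095,
               tolerance = 1e-6)        # infinite-length limit is c
  # strictly decreasing in L for a, b > 0
  L <- c(100, 1000, 10000, 1e5, 1e6)
  expect_true(all(diff(evaluate_sampling_error(fit, L)) < 0))
  expect_error(evaluate_sampling_error(fit, 0), "positive")
})

test_that("profile TSV round-trips through write/read", {
  set.seed(6)
  profiles <- lapply(1:4, function(n) {
    scan_sequence(nuc_sequence(paste0("s", n), random_iid_sequence(2000)))
  })
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_profiles_tsv(profiles, path, provenance = c(mode = "dna"))
  back <- read_profiles_tsv(path)
  expect_length(back, 4)
  expect_equal(back[[2]]$gc, profiles[[2]]$gc, tolerance = 1e-6)
  expect_equal(back[[3]]$ratios, profiles[[3]]$ratios, tolerance = 1e-5)
  expect_match(readLines(path, n = 1), "^# mode=dna")
})

test_that("FASTA reading filters short records and maps U to T", {
  path <- tempfile(fileext = ".fa")
  on.exit(unlink(path))
  writeLines(c(">long desc text", strrep("ACGU", 200), ">short",
               "ACGUACGU"), path)
  seqs <- read_fasta(path, mode = "rna", min_length = 100)
  expect_length(seqs, 1)
  expect_equal(seqs[[1]]$id, "long")
  expect_false(grepl("U", seqs[[1]]$bases))
  expect_equal(nchar(seqs[[1]]$bases), 800)
})
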