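make_seq <- function(...) paste(c(...), collapse = "")

test_that("piRNA clustering joins near-identical sequences and splits distant ones", {
  base <- strsplit("ACGTACGTACGTACGTACGTACGTACGTAC", "")[[1]]  # 30 nt
  one_off <- base; one_off[15] <- "T"
  distant <- rep(c("A", "T"), 15)
  seqs <- c(p1 = make_seq(base), p2 = make_seq(base),
            p3 = make_seq(one_off), p4 = make_seq(distant))
  cl <- cluster_pirnas(seqs, identity_threshold = 0.90)
  expect_equal(cl$cluster_id[1], cl$cluster_id[2])   # identical
  expect_equal(cl$cluster_id[1], cl$cluster_id[3])   # 29/30 = 0.967
  expect_false(cl$cluster_id[4] == cl$cluster_id[1]) # identity ~0.5
})

test_that("single linkage chains clusters through intermediate sequences", {
  a <- strsplit("ACGTACGTACGTACGTACGTACGTACGTAC", "")[[1]]
  b <- a; b[c(3, 9)] <- c("T", "C")    # a-b identity 28/30
  c2 <- b; c2[c(15, 21)] <- c("A", "T") # b-c 28/30, a-c 26/30 < 0.9
  cl <- cluster_pirnas(c(a = make_seq(a), b = make_seq(b),
                         c = make_seq(c2)), 0.90)
  expect_length(unique(cl$cluster_id), 1)
  # complete linkage splits the chain ends
  cl2 <- cluster_pirnas(c(a = make_seq(a), b = make_seq(b),
                          c = make_seq(c2)), 0.90, linkage = "complete")
  expect_gt(length(unique(cl2$cluster_id)), 1)
})

test_that("clustering validates its inputs", {
  expect_error(cluster_pirnas(c(a = "")), "empty")
  expect_error(cluster_pirnas(c(a = "ACGT"), identity_threshold = 0),
               "identity_threshold")
  expect_error(cluster_pirnas(c(a = "ACGT", b = "AXGT")), "alphabet")
  # U is accepted as T
  cl <- cluster_pirnas(c(a = "ACGUACGUACGU", b = "ACGTACGTACGT"), 0.9)
  expect_length(unique(cl$cluster_id), 1)
})

test_that("cluster collapse sums counts and conserves per-sample piRNA totals", {
  for (s in 1:3) {
    cfg <- tiny_config(seed = s)
    m <- simulate_counts(generate_cohort(cfg))
    seqs <- m$features$sequence[m$features$category == "piRNA"]
    names(seqs) <- m$features$feature_id[m$features$category == "piRNA"]
    cl <- cluster_pirnas(seqs)
    out <- collapse_pirna_clusters(m, cl)
    expect_equal(colSums(out$counts[out$features$category == "wiRNA", ,
                                    drop = FALSE]),
                 colSums(m$counts[m$features$category == "piRNA", ,
                                  drop = FALSE]))
    # non-piRNA rows pass through untouched
    expect_equal(out$counts[out$features$category == "miRNA", ],
                 m$counts[m$features$category == "miRNA", ])
  }
})

test_that("low-count filtering implements the per-category 0.01% rule", {
  counts <- rbind(
    big = c(5e5, 499850),  # category total 1e6 with the two below
    just_below = c(25, 25),    # aggregate 50  < 100 -> removed
    just_above = c(75, 75))    # aggregate 150 >= 100 -> retained
  colnames(counts) <- c("s1", "s2")
  m <- ncrna_counts(counts, rep("miRNA", 3))
  f <- filter_low_counts(m, 1e-4)
  expect_setequal(f$features$feature_id, c("big", "just_above"))
  expect_equal(attr(f, "n_removed"), 1)

  # equal-abundance features are never removed
  eq <- ncrna_counts(matrix(100, 5, 3, dimnames = list(paste0("f", 1:5),
                                                       paste0("s", 1:3))),
                     rep(c("miRNA", "snoRNA"), c(3, 2)))
  expect_equal(nrow(filter_low_counts(eq)$counts), 5)
  # min_fraction = 0 is the identity
  expect_equal(filter_low_counts(m, 0)$counts, m$counts)
  em <- ncrna_counts(matrix(1, 1, 1, dimnames = list("f", "s")), "miRNA")
  em$counts <- em$counts[, 0, drop = FALSE]
  expect_error(filter_low_counts(em), "empty")
})

test_that("filtering never removes a feature holding its category share", {
  for (s in 1:5) {
    m0 <- null_count_matrix(p = 40, n = 8, seed = s)
    m <- ncrna_counts(m0, rep(c("miRNA", "piRNA"), each = 20))
    frac <- 0.02
    f <- filter_low_counts(m, frac)
    totals <- rowSums(m0)
    cat_tot <- tapply(totals, m$features$category, sum)
    should_keep <- totals >= frac * cat_tot[m$features$category]
    expect_setequal(f$features$feature_id, rownames(m0)[should_keep])
  }
})

test_that("total sum scaling produces per-sample proportions", {
  m <- ncrna_counts(matrix(c(3, 1), 2, 1, dimnames = list(c("a", "b"), "s1")),
                    c("miRNA", "miRNA"))
  expect_equal(unname(tss_normalize(m)[, 1]), c(0.75, 0.25))
  m2 <- null_count_matrix(30, 10, seed = 2)
  expect_true(all(abs(colSums(tss_normalize(m2)) - 1) < 1e-12))
  # feature permutation equivariance
  perm <- sample(nrow(m2))
  expect_equal(tss_normalize(m2)[perm, ], tss_normalize(m2[perm, ]))
  m3 <- m2; m3[, 4] <- 0
  colnames(m3) <- paste0("smp", 1:10)
  expect_error(tss_normalize(m3), "smp4")
})

test_that("the inverse hyperbolic sine transform matches its closed form", {
  expect_equal(asinh_transform(0), 0)
  expect_equal(asinh_transform(1), log(1 + sqrt(2)), tolerance = 1e-12)
  x <- sort(runif(50, 0, 10))
  y <- asinh_transform(x)
  expect_true(all(diff(y) > 0))
  expect_equal(y, log(x + sqrt(x^2 + 1)))
  expect_error(asinh_transform(c(1, Inf)), "finite")
})

test_that("the preprocessing pipeline is ordered and rejects re-processing", {
  cfg <- tiny_config(seed = 7)
  m <- simulate_counts(generate_cohort(cfg))
  pre <- preprocess_counts(m)
  expect_true(all(pre$matrix >= 0))
  expect_false(any(pre$counts$features$category == "piRNA"))
  expect_true(any(pre$counts$features$category == "wiRNA"))
  # pre-asinh proportions of retained features sum to 1
  expect_true(all(abs(colSums(sinh(pre$matrix)) - 1) < 1e-8))
  # double application is rejected: processed values are not integers
  expect_error(ncrna_counts(pre$matrix, pre$counts$features$category),
               "integer")
})
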