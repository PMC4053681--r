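# OTU clustering, rarefaction, diversity and UniFrac/UPGMA comparisons.

test_that("complete-linkage OTUs match hand-checked small cases", {
  # two identical sequences collapse at any cutoff
  S2 <- matrix(1, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_identical(nrow(cluster_otus(S2, 0.99)$counts), 1L)

  # d(a,b)=0.05, d(a,c)=d(b,c)=0.2, cutoff 0.90 -> {a,b} {c}
  S3 <- 1 - rbind(c(0, .05, .2), c(.05, 0, .2), c(.2, .2, 0))
  dimnames(S3) <- list(c("a", "b", "c"), c("a", "b", "c"))
  tab <- cluster_otus(S3, 0.90)
  expect_identical(unname(tab$membership[c("a", "b", "c")]),
                   c("OTU001", "OTU001", "OTU002"))
  expect_identical(unname(tab$representatives), c("a", "c"))

  expect_error(cluster_otus(S3, 1.2), "cutoff")
})

test_that("clustering equals the brute-force complete-linkage oracle", {
  for (case in list(c(n = 12, seed = 1), c(n = 25, seed = 2),
                    c(n = 40, seed = 3))) {
    S <- random_similarity(case[["n"]], case[["seed"]])
    got <- cluster_otus(S, 0.9)
    mine <- membership_to_partition(got$membership[rownames(S)])
    ref <- oracle_complete_linkage(S, 0.9)
    expect_identical(partition_key(mine), partition_key(ref))
  }
})

test_that("rarefaction keeps exactly n sequences per sample, reproducibly", {
  set.seed(1)
  counts <- cbind(S1 = rmultinom(1, 73, rep(1, 30))[, 1],
                  S2 = rmultinom(1, 93, rep(1, 30))[, 1])
  rownames(counts) <- sprintf("OTU%03d", 1:30)
  tab <- otu_table_coxl(counts)
  sub <- subsample_otu_table(tab, 24, seed = 5)
  expect_equal(unname(colSums(sub$counts)), c(24, 24))
  expect_identical(subsample_otu_table(tab, 24, seed = 5)$counts,
                   sub$counts)

  # at the full library size the table is unchanged up to row pruning
  one <- otu_table_coxl(counts[, 1, drop = FALSE])
  full <- subsample_otu_table(one, 73, seed = 2)
  kept <- rownames(one$counts)[one$counts[, 1] > 0]
  expect_identical(rownames(full$counts), kept)
  expect_equal(unname(full$counts[, 1]), unname(one$counts[kept, 1]))

  expect_error(subsample_otu_table(tab, 80, seed = 1), "S1")
})

test_that("diversity indices match the defining sums", {
  # 24 singleton OTUs: uniform case
  uni <- otu_table_coxl(matrix(1L, 24, 1, dimnames = list(NULL, "u")))
  du <- otu_diversity(uni)
  expect_equal(du$shannon_h, log(24), tolerance = 1e-12)
  expect_equal(du$simpson_d, 1 / 24, tolerance = 1e-12)

  # single OTU: zero entropy, full dominance
  one <- otu_table_coxl(matrix(24L, 1, 1, dimnames = list(NULL, "o")))
  d1 <- otu_diversity(one)
  expect_identical(d1$shannon_h, 0)
  expect_identical(d1$simpson_d, 1)

  # known composition against the hand-written sums
  p <- c(12, 6, 4, 2) / 24
  tab <- otu_table_coxl(matrix(c(12L, 6L, 4L, 2L), 4, 1,
                               dimnames = list(NULL, "k")))
  dk <- otu_diversity(tab)
  expect_equal(dk$shannon_h, -sum(p * log(p)), tolerance = 1e-12)
  expect_equal(dk$simpson_d, sum(p^2), tolerance = 1e-12)
  expect_equal(dk$simpson_complement, 1 - sum(p^2), tolerance = 1e-12)
  expect_equal(dk$simpson_inverse, 1 / sum(p^2), tolerance = 1e-12)

  # invariance to OTU relabelling
  perm <- otu_table_coxl(matrix(c(2L, 12L, 6L, 4L), 4, 1,
                                dimnames = list(NULL, "k")))
  expect_equal(otu_diversity(perm)[-1], dk[-1])

  # pooled per-group indices
  two <- otu_table_coxl(matrix(c(3L, 1L, 0L, 2L), 2, 2,
                               dimnames = list(NULL, c("a", "b"))))
  pooled <- otu_diversity(two, groups = c(a = "g", b = "g"))
  expect_equal(pooled$n_sequences[pooled$scope == "group"], 6)
})

test_that("unweighted UniFrac has metric sanity and the disjoint-subtree limit", {
  tr <- ape::read.tree(text = paste0(
    "((f1:0.1,f2:0.1,f3:0.1,f4:0.1):0.5,",
    "(m1:0.1,m2:0.1,m3:0.1,m4:0.1):0.5);"))
  map <- data.frame(seq_id = tr$tip.label,
                    sample_id = rep(c("F", "M"), each = 4))
  d <- unifrac_distance(tr, map)
  expect_identical(unname(diag(d)), c(0, 0))
  expect_equal(d["F", "M"], 1)   # disjoint subtrees meeting at the root
  expect_identical(d, t(d))
})

test_that("UniFrac equals an independent implementation on random trees", {
  skip_if_not_installed("picante")
  for (s in 1:5) {
    set.seed(s)
    tr <- ape::rtree(20)
    map <- data.frame(seq_id = tr$tip.label,
                      sample_id = sample(c("A", "B", "C"), 20,
                                         replace = TRUE))
    if (length(unique(map$sample_id)) < 3) next
    d <- unifrac_distance(tr, map)
    comm <- t(unclass(table(map$sample_id,
                            factor(map$seq_id, levels = tr$tip.label))))
    ref <- as.matrix(picante::unifrac(t(comm), tr))
    expect_equal(d, ref[rownames(d), colnames(d)], tolerance = 1e-12)
  }
})

test_that("UniFrac input contracts: unmapped leaves, missing tips, zero union", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  map3 <- data.frame(seq_id = c("a", "b", "c"),
                     sample_id = c("X", "X", "Y"))
  expect_warning(d <- unifrac_distance(tr, map3), "unmapped")
  expect_true(all(d >= 0 & d <= 1))

  bad <- data.frame(seq_id = c("a", "zz"), sample_id = c("X", "Y"))
  expect_error(unifrac_distance(tr, bad), "zz")

  tz <- tr
  tz$edge.length[] <- 0
  full <- data.frame(seq_id = c("a", "b", "c", "d"),
                     sample_id = c("X", "X", "Y", "Y"))
  expect_error(unifrac_distance(tz, full), "zero union")
})

test_that("UPGMA jackknife supports a planted two-block structure", {
  fs <- sprintf("f%d:0.05", 1:12)
  ms <- sprintf("m%d:0.05", 1:12)
  tr <- ape::read.tree(text = sprintf("((%s):0.8,(%s):0.8);",
                                      paste(fs, collapse = ","),
                                      paste(ms, collapse = ",")))
  map <- data.frame(seq_id = tr$tip.label,
                    sample_id = c(rep(c("F1", "F2"), 6),
                                  rep(c("M1", "M2"), 6)))
  jk <- upgma_jackknife(tr, map, keep_frac = 0.75, reps = 100, seed = 2)
  sup <- setNames(jk$support$support, jk$support$clade)
  # the forest-vs-monoculture split is recovered in nearly every replicate
  expect_gte(sup[["F1|F2"]] , 0.95)
  expect_gte(sup[["M1|M2"]] , 0.95)

  # keep_frac = 1: every replicate identical, support 1 everywhere
  jk1 <- upgma_jackknife(tr, map, keep_frac = 1, reps = 10, seed = 1)
  expect_true(all(jk1$support$support == 1))
  expect_identical(jk1$n_degenerate, 0L)

  expect_error(upgma_jackknife(tr, map, keep_frac = 0, reps = 5), "keep_frac")
})
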