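test_that("generated datasets have the requested shape and exact class counts", {
  spec <- genotype_spec(n_snps = 40, n_cases = 30, n_controls = 50,
                        missing_rate = 0.03, seed = 5)
  ds <- generate_genotypes(spec)
  expect_identical(dim(ds), c(40L, 80L))
  expect_equal(sum(ds$phenotype == 1L), 30L)
  expect_equal(sum(ds$phenotype == 0L), 50L)
  expect_true(all(is.na(ds$genotypes) | ds$genotypes %in% 0:2))
  # identical seed, identical dataset; different seed differs
  expect_identical(generate_genotypes(spec), ds)
  expect_false(identical(
    generate_genotypes(genotype_spec(40, 30, 50, missing_rate = 0.03, seed = 6)),
    ds))
  # missing_rate = 0 means complete data
  expect_false(anyNA(generate_genotypes(genotype_spec(40, 30, 50, seed = 5))$genotypes))
})

test_that("the default spec reproduces the candidate-gene panel shape", {
  ds <- generate_genotypes(genotype_spec(seed = 1))
  expect_identical(dim(ds), c(1422L, 1282L))
  expect_equal(sum(ds$phenotype == 1L), 491L)
  expect_equal(sum(ds$phenotype == 0L), 791L)
})

test_that("genotype spec validation rejects infeasible inputs", {
  expect_error(genotype_spec(maf_range = c(0, 0.5)), "maf_range")
  expect_error(genotype_spec(missing_rate = 0.6), "missing_rate")
  expect_error(genotype_spec(n_snps = 10,
                             planted_pairs = list(planted_pair(3, 11))),
               "within")
  expect_error(genotype_spec(n_snps = 10,
                             planted_pairs = list(planted_pair(3, 3))),
               "distinct")
  expect_error(planted_pair(1, 2, "xor", effect = 1.5), "effect")
  expect_error(penetrance_table("nonsense"), "arg")
})

test_that("XOR penetrance is purely epistatic: zero marginals at MAF 0.5", {
  # analytic check on the population distribution, not a sample
  pen <- penetrance_table("xor", effect = 1)
  hw <- c(0.25, 0.5, 0.25)
  joint_a_c <- matrix(0, 3, 2)  # P(A = a, C = c)
  for (a in 1:3) for (b in 1:3) {
    pr <- hw[a] * hw[b]
    joint_a_c[a, 2] <- joint_a_c[a, 2] + pr * pen[a, b]
    joint_a_c[a, 1] <- joint_a_c[a, 1] + pr * (1 - pen[a, b])
  }
  expect_equal(oracle_mi_dist(joint_a_c), 0, tolerance = 1e-12)
  # and the joint variable is fully informative: I(A,B;C) = H(C) = 1 bit
  joint_ab_c <- matrix(0, 9, 2)
  k <- 0
  for (a in 1:3) for (b in 1:3) {
    k <- k + 1
    joint_ab_c[k, 2] <- hw[a] * hw[b] * pen[a, b]
    joint_ab_c[k, 1] <- hw[a] * hw[b] * (1 - pen[a, b])
  }
  expect_equal(oracle_mi_dist(joint_ab_c), 1, tolerance = 1e-12)
})

test_that("threshold penetrance has positive marginal MI and positive IG", {
  pen <- penetrance_table("threshold", effect = 0.5)
  hw <- c(0.25, 0.5, 0.25)
  joint_a_c <- matrix(0, 3, 2)
  joint_ab_c <- matrix(0, 9, 2)
  k <- 0
  for (a in 1:3) for (b in 1:3) {
    k <- k + 1
    pr <- hw[a] * hw[b]
    joint_a_c[a, 2] <- joint_a_c[a, 2] + pr * pen[a, b]
    joint_a_c[a, 1] <- joint_a_c[a, 1] + pr * (1 - pen[a, b])
    joint_ab_c[k, 2] <- pr * pen[a, b]
    joint_ab_c[k, 1] <- pr * (1 - pen[a, b])
  }
  mi_marg <- oracle_mi_dist(joint_a_c)
  ig <- oracle_mi_dist(joint_ab_c) - 2 * mi_marg  # marginals equal by symmetry
  expect_gt(mi_marg, 0.01)
  expect_gt(ig, 0.01)
})

test_that("planted XOR pair at MAF 0.5 leaves marginal MI near zero", {
  ds <- generate_genotypes(genotype_spec(
    n_snps = 4, n_cases = 4000, n_controls = 6000,
    planted_pairs = list(planted_pair(1, 2, "xor", 1)), seed = 12))
  mi1 <- mutual_information(ds$genotypes[1, ], ds$phenotype)
  mi2 <- mutual_information(ds$genotypes[2, ], ds$phenotype)
  expect_lt(mi1, 0.01)
  expect_lt(mi2, 0.01)
  # weighted case selection under 0/1 penetrance links C to the parity but
  # not deterministically (cases are a draw from the high-risk stratum), so
  # the pair IG is large without reaching the full 1 bit
  expect_gt(information_gain(ds$genotypes[1, ], ds$genotypes[2, ],
                             ds$phenotype), 0.5)
})

test_that("plant_epistatic_pair regenerates phenotype from the penetrance table", {
  ds <- generate_genotypes(genotype_spec(n_snps = 6, n_cases = 400,
                                         n_controls = 400, seed = 3))
  out <- plant_epistatic_pair(ds, 2, 5, "xor", effect = 1, seed = 9)
  # deterministic XOR at effect 1: phenotype equals the dosage parity
  parity <- (out$genotypes[2, ] + out$genotypes[5, ]) %% 2
  expect_equal(out$phenotype, as.integer(parity))
  # effect 0 gives pure label noise, indistinguishable from unplanted pairs
  noise <- plant_epistatic_pair(ds, 2, 5, "xor", effect = 0, seed = 9)
  expect_lt(abs(information_gain(noise$genotypes[2, ], noise$genotypes[5, ],
                                 noise$phenotype)), 0.05)
  expect_error(plant_epistatic_pair(ds, 2, 5, "no_such_model"), "arg")
})

test_that("estimated IG of an XOR-planted pair exceeds the background 99th percentile", {
  ds <- generate_genotypes(genotype_spec(
    n_snps = 30, n_cases = 500, n_controls = 500,
    planted_pairs = list(planted_pair(4, 9, "xor", 1)), seed = 77))
  sc <- all_pairs_ig(ds)
  up <- sc$ig[upper.tri(sc$ig)]
  planted <- sc$ig[4, 9]
  background <- up[up != planted]
  expect_gt(planted, quantile(background, 0.99))
})

test_that("SNP-to-gene maps are total, many-to-one and cover every gene", {
  map <- generate_snp_gene_map(1422, 396, seed = 2)
  expect_equal(nrow(map), 1422L)
  expect_equal(length(unique(map$gene_id)), 396L)
  expect_equal(sum(table(map$gene_id)), 1422L)
  # bijection when counts match; sizes sum to n_snps in general
  bij <- generate_snp_gene_map(5, 5, seed = 1)
  expect_equal(sort(table(bij$gene_id), decreasing = TRUE)[[1]], 1L)
  small <- generate_snp_gene_map(6, 2, seed = 1)
  expect_equal(sum(table(small$gene_id)), 6L)
  expect_error(generate_snp_gene_map(3, 5), "exceed")
})

test_that("attributed network generator respects the spec and plants structure", {
  spec <- network_spec(50, 100, 8, "random", seed = 4)
  an <- generate_attributed_network(spec)
  expect_equal(igraph::vcount(an$graph), 50L)
  expect_equal(igraph::ecount(an$graph), 100L)
  expect_equal(sum(an$labels == 1L), 8L)
  expect_identical(generate_attributed_network(spec)$labels, an$labels)
  expect_error(network_spec(10, 100, 3), "exceeds")
  # dyadic regime inflates m11 relative to the random expectation
  dyadic_m11 <- vapply(1:40, function(r) {
    a <- generate_attributed_network(network_spec(100, 200, 10, "dyadic",
                                                  strength = 5, seed = r))
    count_dyads(a$graph, a$labels)$m11
  }, numeric(1))
  expect_gt(mean(dyadic_m11), 2 * expected_dyads(100, 200, 10)[["m11_expected"]])
})

test_that("random-regime m11 matches its closed-form expectation over replicates", {
  m11 <- vapply(1:300, function(r) {
    a <- generate_attributed_network(network_spec(40, 80, 10, "random", seed = r))
    count_dyads(a$graph, a$labels)$m11
  }, numeric(1))
  expected <- expected_dyads(40, 80, 10)[["m11_expected"]]
  se <- sd(m11) / sqrt(length(m11))
  expect_lt(abs(mean(m11) - expected), 3 * se)
})

test_that("category generator honours sizes, overlap and determinism", {
  genes <- sprintf("g%03d", 1:185)
  cats <- generate_categories(genes, 808, size_range = c(3, 48), seed = 6)
  expect_length(cats, 808L)
  expect_true(all(lengths(cats) >= 3 & lengths(cats) <= 48))
  expect_true(all(unlist(cats) %in% genes))
  fixed <- generate_categories(genes, 20, size_range = c(3, 3), seed = 1)
  expect_true(all(lengths(fixed) == 3L))
  # no duplicate members within one category
  expect_true(all(vapply(cats, function(m) !anyDuplicated(m), logical(1))))
  expect_error(generate_categories(character(), 5), "non-empty")
  expect_error(
    generate_categories(genes, 100, size_range = c(40, 50),
                        overlap_allowed = FALSE), "exceed")
  expect_identical(generate_categories(genes, 10, seed = 3),
                   generate_categories(genes, 10, seed = 3))
})
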