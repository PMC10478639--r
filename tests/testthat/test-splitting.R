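test_that("coordinate clustering recovers two well-separated blobs", {
  m <- two_blob_model(n_per = 60, sep = 50, seed = 1)
  truth <- rep(1:2, each = 60)
  part <- split_by_coordinates(m, 2)
  expect_equal(adjusted_rand_index(part$domain, truth), 1)
  # k = 1 puts every residue in one domain
  p1 <- split_by_coordinates(m, 1)
  expect_equal(unique(p1$domain), 1L)
  expect_error(split_by_coordinates(line_model(3), 4), "too many clusters")
})

test_that("partitions are disjoint, exhaustive and deterministic", {
  for (seed in c(2, 5, 9)) {
    fx <- generate_model(synthetic_spec(n_domains = 2, seed = seed))
    for (k in 1:3) {
      part <- split_by_coordinates(fx$model, k, min_domain = 5)
      lab <- part$domain
      expect_false(anyNA(lab))
      expect_setequal(unique(lab), seq_len(max(lab)))
      expect_equal(length(lab), nrow(residues(fx$model)))
      # domain ids are numbered by ascending first residue index
      firsts <- vapply(seq_len(max(lab)), function(d) min(which(lab == d)), 1L)
      expect_true(all(diff(firsts) > 0))
    }
    p_a <- split_by_coordinates(fx$model, 2)
    p_b <- split_by_coordinates(fx$model, 2)
    expect_identical(p_a$domain, p_b$domain)
    k_a <- split_by_coordinates(fx$model, 2, linkage = "kmeans", seed = 7)
    k_b <- split_by_coordinates(fx$model, 2, linkage = "kmeans", seed = 7)
    expect_identical(k_a$domain, k_b$domain)
  }
})

test_that("PAE block matrices split exactly into their planted blocks", {
  # inter-block error above the edge cutoff disconnects the graph, so the
  # planted partition is forced
  for (k in 1:3) {
    sizes <- rep(45, k)
    part <- split_by_pae(line_model(sum(sizes)), block_pae(sizes))
    expect_equal(adjusted_rand_index(part$domain, rep(seq_len(k), sizes)), 1)
  }
  # uniform low error leaves nothing to separate
  u <- pae_matrix({m <- matrix(2, 50, 50); diag(m) <- 0; m})
  pu <- split_by_pae(line_model(50), u)
  expect_equal(unique(pu$domain), 1L)
  expect_error(split_by_pae(line_model(10), block_pae(c(45, 45))),
               "PAE/model length mismatch")
  # repeated runs are identical
  p1 <- split_by_pae(line_model(90), block_pae(c(45, 45)))
  p2 <- split_by_pae(line_model(90), block_pae(c(45, 45)))
  expect_identical(p1$domain, p2$domain)
})

test_that("greedy modularity agrees with an independent implementation", {
  skip_if_not_installed("igraph")
  withr::with_seed(42, {
    for (rep in 1:5) {
      n <- 30
      lab <- rep(1:2, each = n / 2)
      w <- ifelse(outer(lab, lab, "=="), 1, 0) * matrix(runif(n * n, 0.5, 1), n)
      w[outer(lab, lab, "!=")] <- runif(sum(outer(lab, lab, "!=")), 0, 0.08)
      w <- (w + t(w)) / 2
      diag(w) <- 0
      g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                               weighted = TRUE)
      ref <- as.integer(igraph::membership(igraph::cluster_fast_greedy(g)))
      mine <- mrprep:::greedy_modularity(w, resolution = 1)
      expect_equal(adjusted_rand_index(ref, mine), 1)
    }
  })
})

test_that("the default sweep returns the k = 1, 2, 3 partitions in order", {
  fx <- generate_model(synthetic_spec(n_domains = 3, domain_sizes = 66,
                                      separation = 55, linker_lengths = 12,
                                      seed = 4))
  sweep <- default_split_sweep(fx$model)
  expect_length(sweep, 3)
  expect_equal(vapply(sweep, function(p) max(p$domain), 1L), 1:3)
  expect_equal(unique(sweep[[1]]$domain), 1L)
  # infeasible ks are dropped with a warning
  expect_warning(short <- default_split_sweep(line_model(2), min_domain = 1),
                 "truncated")
  expect_length(short, 2)
})

test_that("undersized domains merge into their nearest neighbour", {
  # a 150-residue blob and a 5-residue satellite
  withr::with_seed(3, {
    xyz <- rbind(matrix(rnorm(450, sd = 4), ncol = 3),
                 sweep(matrix(rnorm(15, sd = 1), ncol = 3), 2, c(40, 0, 0), "+"))
  })
  m <- ca_model(xyz, b = 90)
  part <- split_by_coordinates(m, 2, min_domain = 1)
  expect_equal(max(part$domain), 2)
  merged <- enforce_min_domain(part, m, min_domain = 20)
  expect_equal(unique(merged$domain), 1L)
  expect_equal(sum(merged$domain == 1), 155)
  # all-large partitions are untouched; the result is a fixed point
  big <- split_by_coordinates(two_blob_model(seed = 2), 2)
  expect_identical(enforce_min_domain(big, two_blob_model(seed = 2), 20)$domain,
                   big$domain)
  sizes <- tabulate(merged$domain)
  expect_true(all(sizes >= 20) || max(merged$domain) == 1)
})

test_that("extracted search models conserve residues and B values", {
  m <- two_blob_model(n_per = 50, seed = 6, b = round(runif(100, 40, 95), 2))
  part <- split_by_coordinates(m, 2)
  models <- extract_search_models(m, part)
  expect_length(models, 2)
  expect_equal(sum(vapply(models, function(x) nrow(residues(x)), 1L)), 100)
  # conservation: removed + sum of domain sizes equals the input count
  expect_equal(sum(is.na(part$domain)) +
                 sum(vapply(models, function(x) nrow(residues(x)), 1L)),
               nrow(residues(m)))
  recon <- dplyr::arrange(dplyr::bind_rows(models), resno)
  expect_equal(recon$b, m$b)
  expect_equal(recon$x, m$x)
  # a single-domain partition is a copy of the input
  p1 <- split_by_coordinates(m, 1)
  one <- extract_search_models(m, p1)
  expect_equal(nrow(one[[1]]), nrow(m))
  expect_equal(one[[1]]$b, m$b)
})
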