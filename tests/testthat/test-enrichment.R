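test_that("fisher_one_sided handles the degenerate tails", {
  expect_equal(fisher_one_sided(0, 5, 5, 20), 1)
  expect_equal(fisher_one_sided(10, 10, 10, 10), 1)
  expect_error(fisher_one_sided(6, 5, 5, 20), "inconsistent")
  expect_error(fisher_one_sided(3, 5, 2, 20), "inconsistent")
})

test_that("fisher_one_sided matches the enumeration oracle", {
  # the spec-level worked example plus random tables
  expect_equal(fisher_one_sided(4, 5, 5, 20), hyper_tail_oracle(4, 5, 5, 20),
               tolerance = 1e-12)
  set.seed(101)
  for (i in 1:200) {
    N <- sample(2:60, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(fisher_one_sided(k, K, n, N), hyper_tail_oracle(k, K, n, N),
                 tolerance = 1e-10)
  }
})

test_that("bh_adjust matches the step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  p <- c(0.01, 0.02, 0.03)
  expect_equal(bh_adjust(p), bh_oracle(p))
  set.seed(7)
  for (i in 1:100) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("terms matching the seed set are retained, disjoint terms never", {
  universe <- paste0("g", 1:100)
  seeds <- paste0("g", 1:10)
  catalog <- make_catalog(list(src1 = list(
    hit = seeds,                       # exactly the seed set
    miss = paste0("g", 51:60),         # disjoint from seeds
    part = paste0("g", 8:17))))        # partial overlap
  sig <- select_significant_terms(catalog, seeds, universe, level = 0.05)
  tab <- sig$table
  expect_true(tab$retained[tab$term == "hit"])
  expect_false(tab$retained[tab$term == "miss"])
  expect_equal(tab$p[tab$term == "miss"], 1)
  # confirm the retained decision against the enumeration oracle + BH
  p_oracle <- vapply(c("hit", "miss", "part"), function(t) {
    r <- tab[tab$term == t, ]
    hyper_tail_oracle(r$k, r$K, r$n, r$N)
  }, numeric(1))
  expect_equal(tab$adjusted[match(c("hit", "miss", "part"), tab$term)],
               bh_oracle(unname(p_oracle)), tolerance = 1e-10)
})

test_that("level 0 retains nothing and absent seeds error", {
  universe <- paste0("g", 1:50)
  catalog <- make_catalog(list(src1 = list(T1 = paste0("g", 1:5))))
  sig <- select_significant_terms(catalog, paste0("g", 1:5), universe,
                                  level = 0)
  expect_length(sig$F, 0)
  expect_error(select_significant_terms(catalog, "absent", universe),
               "no seed genes")
})

test_that("adding a term with no seed gene never changes F", {
  set.seed(21)
  universe <- paste0("g", 1:80)
  seeds <- paste0("g", 1:8)
  base_terms <- list(T1 = paste0("g", 1:8), T2 = paste0("g", 30:45))
  for (i in 1:5) {
    extra <- sample(paste0("g", 20:80), sample(5:15, 1))
    cat_a <- make_catalog(list(s = base_terms))
    cat_b <- make_catalog(list(s = c(base_terms, list(EXTRA = extra))))
    Fa <- select_significant_terms(cat_a, seeds, universe, level = 1e-3)$F
    Fb <- select_significant_terms(cat_b, seeds, universe, level = 1e-3)$F
    expect_setequal(Fa, Fb)
  }
})

test_that("per-source vs pooled BH adjust over the stated families", {
  universe <- paste0("g", 1:60)
  seeds <- paste0("g", 1:6)
  catalog <- make_catalog(list(
    a = list(T1 = seeds, T2 = paste0("g", 40:50)),
    b = list(U1 = paste0("g", 4:9), U2 = paste0("g", 30:39),
             U3 = paste0("g", 10:20))))
  per <- select_significant_terms(catalog, seeds, universe, level = 1)$table
  pooled <- select_significant_terms(catalog, seeds, universe, level = 1,
                                     adjust_scope = "pooled")$table
  expect_equal(per$adjusted[per$source == "a"],
               bh_oracle(per$p[per$source == "a"]))
  expect_equal(pooled$adjusted, bh_oracle(pooled$p))
})

test_that("theta gives seeds the constant and scores overlap per source", {
  catalog <- make_catalog(list(
    s1 = list(A = c("x", "y"), B = c("x", "z"), C = c("w"), D = c("v")),
    s2 = list(E = c("x", "q"), F = c("q"))))
  sig <- make_sig(list(s1 = tid("s1", c("A", "B", "C", "D")),
                       s2 = tid("s2", c("E", "F"))))
  universe <- c("seed1", "x", "y", "q", "none")
  theta <- compute_theta(catalog, sig, seeds = "seed1", universe,
                         ell = 1000)
  expect_equal(unname(theta["seed1"]), 1000)
  # |A(x) n F1| = 2 of 4, |A(x) n F2| = 1 of 2 -> 0.5 + 0.5 = 1
  expect_equal(unname(theta["x"]), 1)
  expect_equal(unname(theta["y"]), 0.25)
  expect_equal(unname(theta["none"]), 0)
  expect_error(compute_theta(catalog, sig, "seed1", universe, ell = 2),
               "must exceed")
})

test_that("seed priority: every non-seed theta is below l, seeds get ell", {
  set.seed(5)
  genes <- paste0("g", 1:40)
  catalog <- make_catalog(list(
    s1 = setNames(lapply(1:6, function(i) sample(genes, 8)),
                  paste0("T", 1:6)),
    s2 = setNames(lapply(1:4, function(i) sample(genes, 8)),
                  paste0("U", 1:4))))
  sig <- make_sig(list(s1 = tid("s1", paste0("T", 1:6)),
                       s2 = tid("s2", paste0("U", 1:4))))
  seeds <- c("g1", "g2")
  theta <- compute_theta(catalog, sig, seeds, genes, ell = 1000)
  non_seed <- setdiff(genes, seeds)
  expect_lte(max(theta[non_seed]), 2)      # l = 2 sources
  expect_equal(unname(theta[seeds]), c(1000, 1000))
  expect_gt(min(theta[seeds]), max(theta[non_seed]))
})
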