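# simulate a discrete chain A -> B -> C with strong links
chain_data <- function(n, seed) {
  set.seed(seed)
  a <- sample(1:3, n, replace = TRUE)
  flip <- function(parent) {
    ifelse(stats::runif(n) < 0.85, parent, sample(1:3, n, replace = TRUE))
  }
  data.frame(A = a, B = flip(a), C = NA)[, 1:2] -> d
  d$C <- flip(d$B)
  d
}

test_that("degenerate structures are handled", {
  d <- chain_data(200, 1)
  bn0 <- learn_bn(d, max_parents = 0)
  expect_equal(nrow(bn0$edges), 0L)
  bn1 <- learn_bn(d["A"], max_parents = 2)
  expect_equal(nrow(bn1$edges), 0L)
  expect_true(bn_is_acyclic(bn1))
})

test_that("hill climbing recovers the chain skeleton in most seeds", {
  hits <- 0L
  for (seed in 1:10) {
    d <- chain_data(5000, seed)
    bn <- learn_bn(d, max_parents = 2)
    und <- paste(pmin(bn$edges$from, bn$edges$to),
                 pmax(bn$edges$from, bn$edges$to))
    skeleton_ok <- setequal(und, c("A B", "B C"))
    if (skeleton_ok) hits <- hits + 1L
    expect_true(bn_is_acyclic(bn))
    expect_true(all(diff(bn$trajectory) > 0))
  }
  expect_gte(hits, 8L)
})

test_that("the in-degree cap and acyclicity hold on noisy data", {
  set.seed(7)
  d <- as.data.frame(matrix(sample(1:3, 200 * 6, replace = TRUE), 200, 6))
  d$V1 <- d$V2  # force one deterministic dependency
  bn <- learn_bn(d, max_parents = 2)
  indeg <- table(factor(bn$edges$to, levels = bn$nodes))
  expect_true(all(indeg <= 2))
  expect_true(bn_is_acyclic(bn))
})

test_that("naive-Bayes initialization starts from the class star", {
  d <- chain_data(300, 3)
  names(d) <- c("visits", "x1", "x2")
  bn <- learn_bn(d, max_parents = 1, init_as_naive_bayes = TRUE,
                 class_var = "visits")
  expect_true(bn_is_acyclic(bn))
  expect_true(all(diff(bn$trajectory) > 0) || length(bn$trajectory) == 1)
  expect_error(learn_bn(d, init_as_naive_bayes = TRUE, class_var = "zz"),
               class = "opinionpulse_config_error")
})

test_that("the Markov blanket collects parents, children and spouses", {
  edges_to_bn <- function(nodes, edges) {
    amat <- matrix(FALSE, length(nodes), length(nodes),
                   dimnames = list(nodes, nodes))
    for (i in seq_len(nrow(edges))) amat[edges$from[i], edges$to[i]] <- TRUE
    structure(list(nodes = nodes, edges = edges, amat = amat, score = 0,
                   trajectory = 0, params = list()), class = "bn_structure")
  }
  nodes <- c("t", "p", "c", "s", "iso")
  empty <- edges_to_bn(nodes, tibble::tibble(from = character(),
                                             to = character()))
  expect_length(influential_factors(empty, "t"), 0L)

  star <- edges_to_bn(nodes, tibble::tibble(from = "t",
                                            to = c("p", "c", "s")))
  expect_setequal(influential_factors(star, "t"), c("p", "c", "s"))

  vstruct <- edges_to_bn(nodes, tibble::tibble(from = c("p", "t", "s"),
                                               to = c("t", "c", "c")))
  expect_setequal(influential_factors(vstruct, "t"), c("p", "c", "s"))
  expect_error(influential_factors(vstruct, "nope"),
               class = "opinionpulse_config_error")
})

test_that("BDeu family scores agree with a direct likelihood computation", {
  # independent check of the score for a single family via its definition
  d <- chain_data(100, 5)
  data <- vapply(d, as.integer, integer(nrow(d)))
  r <- apply(data, 2, max)
  direct <- function(child, parents, ess = 1) {
    q <- if (length(parents)) prod(r[parents]) else 1L
    total <- 0
    for (j in seq_len(q)) {
      rows <- rep(TRUE, nrow(data))
      if (length(parents)) {
        combo <- arrayInd(j, r[parents])
        for (k in seq_along(parents)) {
          rows <- rows & data[, parents[k]] == combo[k]
        }
      }
      nj <- sum(rows)
      total <- total + lgamma(ess / q) - lgamma(ess / q + nj)
      for (v in seq_len(r[child])) {
        njk <- sum(rows & data[, child] == v)
        total <- total + lgamma(ess / (q * r[child]) + njk) -
          lgamma(ess / (q * r[child]))
      }
    }
    total
  }
  for (case in list(list(3, integer(0)), list(3, 2L), list(1, c(2L, 3L)))) {
    expect_equal(opinionpulse:::bdeu_family_score(data, r, case[[1]],
                                                  case[[2]], ess = 1),
                 unname(direct(case[[1]], case[[2]])))
  }
})
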