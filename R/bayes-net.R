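# Bayesian-network structure learning: greedy hill climbing over
# add/delete/reverse single-edge moves maximizing the BDeu score.

# BDeu family score for `child` given `parents` (column indices).
bdeu_family_score <- function(data, r, child, parents, ess) {
  n <- nrow(data)
  ri <- r[child]
  if (length(parents)) {
    q <- prod(r[parents])
    stride <- cumprod(c(1, r[parents]))[seq_along(parents)]
    j <- 1L + as.integer((data[, parents, drop = FALSE] - 1L) %*% stride)
  } else {
    q <- 1L
    j <- rep.int(1L, n)
  }
  idx <- (j - 1L) * ri + data[, child]
  njk <- tabulate(idx, nbins = q * ri)
  nj <- colSums(matrix(njk, ri, q))
  a_j <- ess / q
  a_jk <- ess / (q * ri)
  sum(lgamma(a_j) - lgamma(a_j + nj)) +
    sum(lgamma(a_jk + njk) - lgamma(a_jk))
}

bn_reaches <- function(amat, from, to) {
  # TRUE if a directed path from -> to exists
  seen <- logical(nrow(amat))
  stack <- from
  while (length(stack)) {
    v <- stack[[1]]
    stack <- stack[-1]
    if (v == to) return(TRUE)
    if (seen[v]) next
    seen[v] <- TRUE
    stack <- c(stack, which(amat[v, ] & !seen))
  }
  FALSE
}

#' Learn a Bayesian-network structure by BDeu hill climbing
#'
#' Greedy search over single-edge additions, deletions and reversals that
#' maximizes the Bayesian-Dirichlet (BDeu) score with equivalent sample
#' size `ess`; in-degree is capped at `max_parents`, cyclic candidates are
#' rejected, and the search stops at a local optimum. The accepted-move
#' score trajectory is strictly non-decreasing and the result is always a
#' DAG.
#'
#' @param ddata Discrete data: a data frame of factors/integer codes
#'   ([discretize_panel()]) with at least two variables.
#' @param max_parents Maximum in-degree (0 yields an empty graph).
#' @param init_as_naive_bayes Start from a naive-Bayes star with
#'   `class_var` as the common parent instead of the empty graph.
#' @param ess Equivalent sample size of the BDeu prior.
#' @param class_var Class variable for the naive-Bayes initialization.
#' @return A list of class `bn_structure`: `nodes`, `edges` (tibble
#'   `from`, `to`), `amat`, `score`, `trajectory`, `params`.
#' @export
learn_bn <- function(ddata, max_parents = 2, init_as_naive_bayes = FALSE,
                     ess = 1.0, class_var = "visits") {
  ddata <- as.data.frame(ddata)
  data <- vapply(ddata, function(col) as.integer(as.factor(col)),
                 integer(nrow(ddata)))
  if (is.null(dim(data))) data <- matrix(data, nrow = nrow(ddata))
  colnames(data) <- names(ddata)
  V <- ncol(data)
  vars <- colnames(data)
  if (V < 1L) abort("no variables.", class = "opinionpulse_config_error")
  r <- apply(data, 2L, max)
  amat <- matrix(FALSE, V, V, dimnames = list(vars, vars))
  if (init_as_naive_bayes && V > 1L && max_parents >= 1L) {
    cls <- match(class_var, vars)
    if (is.na(cls)) {
      abort(sprintf("class variable '%s' not found.", class_var),
            class = "opinionpulse_config_error")
    }
    amat[cls, -cls] <- TRUE
  }

  cache <- new.env(parent = emptyenv())
  fs <- function(child, parents) {
    key <- paste0(child, "|", paste(sort(parents), collapse = ","))
    val <- cache[[key]]
    if (is.null(val)) {
      val <- bdeu_family_score(data, r, child, parents, ess)
      cache[[key]] <- val
    }
    val
  }
  parents_of <- function(j) which(amat[, j])
  total <- sum(vapply(seq_len(V), function(j) fs(j, parents_of(j)), numeric(1)))
  trajectory <- total

  if (V > 1L) {
    repeat {
      best <- list(delta = 1e-9, move = NULL)
      for (j in seq_len(V)) {
        pa <- parents_of(j)
        base_j <- fs(j, pa)
        # additions i -> j
        if (length(pa) < max_parents) {
          for (i in seq_len(V)) {
            if (i == j || amat[i, j] || amat[j, i]) next
            if (bn_reaches(amat, j, i)) next
            delta <- fs(j, c(pa, i)) - base_j
            if (delta > best$delta) {
              best <- list(delta = delta, move = list(type = "add", i = i, j = j))
            }
          }
        }
        # deletions and reversals of i -> j
        for (i in pa) {
          d_del <- fs(j, setdiff(pa, i)) - base_j
          if (d_del > best$delta) {
            best <- list(delta = d_del, move = list(type = "delete", i = i, j = j))
          }
          pa_i <- parents_of(i)
          if (length(pa_i) < max_parents) {
            amat[i, j] <- FALSE
            cyc <- bn_reaches(amat, i, j)
            amat[i, j] <- TRUE
            if (!cyc) {
              d_rev <- d_del + fs(i, c(pa_i, j)) - fs(i, pa_i)
              if (d_rev > best$delta) {
                best <- list(delta = d_rev,
                             move = list(type = "reverse", i = i, j = j))
              }
            }
          }
        }
      }
      if (is.null(best$move)) break
      m <- best$move
      if (m$type == "add") {
        amat[m$i, m$j] <- TRUE
      } else if (m$type == "delete") {
        amat[m$i, m$j] <- FALSE
      } else {
        amat[m$i, m$j] <- FALSE
        amat[m$j, m$i] <- TRUE
      }
      total <- total + best$delta
      trajectory <- c(trajectory, total)
    }
  }
  idx <- which(amat, arr.ind = TRUE)
  edges <- tibble(from = vars[idx[, 1]], to = vars[idx[, 2]])
  structure(list(nodes = vars, edges = edges, amat = amat, score = total,
                 trajectory = trajectory,
                 params = list(max_parents = max_parents, ess = ess,
                               init_as_naive_bayes = init_as_naive_bayes)),
            class = "bn_structure")
}

#' Test a learned structure for acyclicity
#' @param bn A `bn_structure`.
#' @return TRUE if a topological order exists.
#' @export
bn_is_acyclic <- function(bn) {
  amat <- bn$amat
  remaining <- seq_len(nrow(amat))
  while (length(remaining)) {
    indeg <- colSums(amat[remaining, remaining, drop = FALSE])
    free <- remaining[indeg == 0]
    if (!length(free)) return(FALSE)
    remaining <- setdiff(remaining, free)
  }
  TRUE
}

#' Markov blanket of a target variable
#'
#' Returns the parents, children and children's other parents of `target`
#' in the learned structure — the factor set the network deems directly
#' informative about it.
#'
#' @param bn A `bn_structure`.
#' @param target Variable name (default `"visits"`).
#' @return Character vector of variable names (possibly empty).
#' @export
influential_factors <- function(bn, target = "visits") {
  stopifnot(inherits(bn, "bn_structure"))
  t <- match(target, bn$nodes)
  if (is.na(t)) {
    abort(sprintf("target '%s' not in the network.", target),
          class = "opinionpulse_config_error")
  }
  parents <- which(bn$amat[, t])
  children <- which(bn$amat[t, ])
  spouses <- unlist(lapply(children, function(ch) which(bn$amat[, ch])))
  setdiff(bn$nodes[sort(unique(c(parents, children, spouses)))], target)
}

#' @export
print.bn_structure <- function(x, ...) {
  cat(sprintf("<bn_structure> %d nodes, %d edges, BDeu score %.2f\n",
              length(x$nodes), nrow(x$edges), x$score))
  invisible(x)
}
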