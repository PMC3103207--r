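#' BDeu log marginal likelihood of one family (child + parent set)
#'
#' Closed-form Bayesian Dirichlet equivalent uniform score: with q parent
#' configurations, child arity r, hyperparameters `alpha_j = ess / q` and
#' `alpha_jk = ess / (q r)`, the log marginal likelihood is
#' `sum_j [ lgamma(alpha_j) - lgamma(alpha_j + n_j) +
#' sum_k ( lgamma(alpha_jk + n_jk) - lgamma(alpha_jk) ) ]`.
#'
#' @param child column index of the child variable.
#' @param parents integer vector of parent column indices (possibly empty).
#' @param data integer matrix of categorical values; values of variable v
#'   must lie in `1:arity[v]`.
#' @param arity per-variable state counts; defaults to observed maxima.
#' @param ess equivalent sample size of the Dirichlet prior (> 0).
#' @return log marginal likelihood (0 for empty data).
#' @export
bdeu_family_score <- function(child, parents, data, arity = NULL, ess = 1) {
  if (ess <= 0) stop("ess must be positive")
  if (is.null(arity)) arity <- apply(data, 2, max)
  n <- nrow(data)
  if (n == 0) return(0)
  if (anyNA(data)) stop("complete data required")
  r <- arity[child]
  q <- if (length(parents)) prod(arity[parents]) else 1L
  # flat index of the parent configuration per row
  j <- rep(1L, n)
  mult <- 1L
  for (pp in parents) {
    j <- j + (data[, pp] - 1L) * mult
    mult <- mult * arity[pp]
  }
  cell <- j + (data[, child] - 1L) * q
  njk <- tabulate(cell, nbins = q * r)
  nj <- tabulate(j, nbins = q)
  a_jk <- ess / (q * r)
  a_j <- ess / q
  sum(lgamma(a_j) - lgamma(a_j + nj)) +
    sum(lgamma(a_jk + njk) - lgamma(a_jk))
}

total_dag_score <- function(parents_list, data, arity, ess) {
  sum(vapply(seq_along(parents_list), function(i)
    bdeu_family_score(i, parents_list[[i]], data, arity, ess), numeric(1)))
}

#' Optimal Bayesian forest over categorical variables
#'
#' Learns the maximum-score forest (each variable has at most one
#' parent) under the BDeu score.  Edge weights
#' `w(i,j) = score(j | i) - score(j | empty)` are symmetric under
#' likelihood equivalence, so the optimum is a maximum-weight spanning
#' forest over the edges with positive weight (Kruskal's algorithm on
#' all variable pairs, hence quadratic in the number of variables).
#' Each tree is rooted at its lowest-index variable and arcs are
#' directed away from the root.
#'
#' @param data integer matrix of categorical values in `1:arity[v]`.
#' @param arity per-variable arities (default observed maxima).
#' @param ess BDeu equivalent sample size.
#' @return list of class `bn_forest`: `parents` (integer vector, 0 =
#'   none), `arcs` (data.frame parent, child, arc, exp_arc), `score`
#'   (total log marginal likelihood), `weights` (symmetric gain matrix).
#' @export
learn_forest <- function(data, arity = NULL, ess = 1) {
  v <- ncol(data)
  if (is.null(arity)) arity <- apply(data, 2, max)
  s0 <- vapply(seq_len(v), function(j)
    bdeu_family_score(j, integer(0), data, arity, ess), numeric(1))
  W <- matrix(0, v, v, dimnames = list(colnames(data), colnames(data)))
  if (v >= 2) {
    for (i in seq_len(v - 1)) for (j in (i + 1):v)
      W[i, j] <- W[j, i] <-
        bdeu_family_score(j, i, data, arity, ess) - s0[j]
  }
  edges <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  parent_of <- integer(v)
  if (nrow(edges)) {
    ord <- order(W[edges], decreasing = TRUE)
    edges <- edges[ord, , drop = FALSE]
    comp <- seq_len(v)                    # union-find (path halving)
    find <- function(x) { while (comp[x] != x) { comp[x] <<- comp[comp[x]]; x <- comp[x] }; x }
    keep <- matrix(0L, 0, 2)
    for (r in seq_len(nrow(edges))) {
      a <- find(edges[r, 1]); b <- find(edges[r, 2])
      if (a != b) { comp[a] <- b; keep <- rbind(keep, edges[r, ]) }
    }
    # orient each tree away from its lowest-index node
    if (nrow(keep)) {
      adj <- lapply(seq_len(v), function(i) integer(0))
      for (r in seq_len(nrow(keep))) {
        adj[[keep[r, 1]]] <- c(adj[[keep[r, 1]]], keep[r, 2])
        adj[[keep[r, 2]]] <- c(adj[[keep[r, 2]]], keep[r, 1])
      }
      visited <- logical(v)
      for (root in seq_len(v)) {
        if (visited[root] || !length(adj[[root]])) next
        queue <- root; visited[root] <- TRUE
        while (length(queue)) {
          u <- queue[1]; queue <- queue[-1]
          for (w in adj[[u]]) if (!visited[w]) {
            parent_of[w] <- u; visited[w] <- TRUE; queue <- c(queue, w)
          }
        }
      }
    }
  }
  arcs <- forest_arcs(parent_of, W)
  total <- sum(s0) + sum(W[cbind(arcs$parent_idx, arcs$child_idx)])
  structure(list(parents = parent_of, arcs = arcs[c("parent", "child",
                                                    "arc", "exp_arc")],
                 score = total, weights = W,
                 varnames = colnames(data)),
            class = "bn_forest")
}

forest_arcs <- function(parent_of, W) {
  ch <- which(parent_of > 0)
  arc <- W[cbind(parent_of[ch], ch)]
  data.frame(parent = label_var(parent_of[ch], W),
             child = label_var(ch, W),
             arc = arc, exp_arc = vapply(arc, format_exp_arc, character(1)),
             parent_idx = parent_of[ch], child_idx = ch)
}

label_var <- function(idx, W) {
  if (!length(idx)) return(character(0))
  nm <- colnames(W)
  if (is.null(nm)) paste0("X", idx) else nm[idx]
}

#' Greedy hill-climbing search over DAG structures
#'
#' Best-improvement hill climbing with add / delete / reverse arc moves
#' under the decomposable BDeu score, starting from the empty graph
#' (restart 1) and from random DAGs (further restarts); the best local
#' optimum over all restarts is returned.  The arc strength of `i -> j`
#' in the final DAG is the local score drop from removing it:
#' `score(j | G_j) - score(j | G_j without i)`.
#'
#' @param data integer matrix of categorical values in `1:arity[v]`.
#' @param arity per-variable arities (default observed maxima).
#' @param ess BDeu equivalent sample size.
#' @param restarts number of restarts (>= 1).
#' @param seed optional RNG seed for the random restarts.
#' @param max_parents cap on parent-set size (default unlimited).
#' @return list of class `bn_dag`: `parents` (list of parent index
#'   vectors), `arcs` (data.frame parent, child, arc, exp_arc), `score`.
#' @export
greedy_dag_search <- function(data, arity = NULL, ess = 1, restarts = 5,
                              seed = NULL, max_parents = Inf) {
  if (restarts < 1) stop("restarts must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  v <- ncol(data)
  if (is.null(arity)) arity <- apply(data, 2, max)
  cache <- new.env(hash = TRUE, parent = emptyenv())
  fam <- function(j, pa) {
    key <- paste0(j, "|", paste(sort(pa), collapse = ","))
    val <- cache[[key]]
    if (is.null(val)) {
      val <- bdeu_family_score(j, pa, data, arity, ess)
      cache[[key]] <- val
    }
    val
  }
  climb <- function(parents) {
    fs <- vapply(seq_len(v), function(j) fam(j, parents[[j]]), numeric(1))
    repeat {
      best_delta <- 0; best_move <- NULL
      for (j in seq_len(v)) {
        pa <- parents[[j]]
        for (i in seq_len(v)) {
          if (i == j) next
          if (i %in% pa) {
            # delete i -> j
            d <- fam(j, setdiff(pa, i)) - fs[j]
            if (d > best_delta) { best_delta <- d; best_move <- list("del", i, j) }
            # reverse i -> j
            if (!(j %in% parents[[i]]) &&
                length(parents[[i]]) < max_parents &&
                !creates_cycle(parents, j, i, drop = c(i, j))) {
              d <- (fam(j, setdiff(pa, i)) - fs[j]) +
                   (fam(i, c(parents[[i]], j)) - fs[i])
              if (d > best_delta) { best_delta <- d; best_move <- list("rev", i, j) }
            }
          } else if (length(pa) < max_parents &&
                     !creates_cycle(parents, i, j)) {
            d <- fam(j, c(pa, i)) - fs[j]
            if (d > best_delta) { best_delta <- d; best_move <- list("add", i, j) }
          }
        }
      }
      if (is.null(best_move)) break
      i <- best_move[[2]]; j <- best_move[[3]]
      if (best_move[[1]] == "add") {
        parents[[j]] <- c(parents[[j]], i)
      } else if (best_move[[1]] == "del") {
        parents[[j]] <- setdiff(parents[[j]], i)
      } else {
        parents[[j]] <- setdiff(parents[[j]], i)
        parents[[i]] <- c(parents[[i]], j)
      }
      fs <- vapply(seq_len(v), function(jj) fam(jj, parents[[jj]]), numeric(1))
    }
    list(parents = parents, score = sum(fs))
  }
  best <- NULL
  for (r in seq_len(restarts)) {
    start <- if (r == 1) replicate(v, integer(0), simplify = FALSE)
             else random_dag(v, max_parents)
    res <- climb(start)
    if (is.null(best) || res$score > best$score) best <- res
  }
  arcs <- do.call(rbind, lapply(seq_len(v), function(j) {
    pa <- best$parents[[j]]
    if (!length(pa)) return(NULL)
    arc <- vapply(pa, function(i)
      fam(j, pa) - fam(j, setdiff(pa, i)), numeric(1))
    data.frame(parent = label_var(pa, matrix(0, v, v,
                 dimnames = list(colnames(data), colnames(data)))),
               child = label_var(rep(j, length(pa)), matrix(0, v, v,
                 dimnames = list(colnames(data), colnames(data)))),
               arc = arc,
               exp_arc = vapply(arc, format_exp_arc, character(1)))
  }))
  if (is.null(arcs))
    arcs <- data.frame(parent = character(), child = character(),
                       arc = numeric(), exp_arc = character())
  structure(list(parents = best$parents, arcs = arcs, score = best$score,
                 varnames = colnames(data)),
            class = "bn_dag")
}

# would adding edge from -> to create a directed cycle?  `drop` optionally
# removes an existing edge (used when testing a reversal).
creates_cycle <- function(parents, from, to, drop = NULL) {
  # cycle iff `from` is reachable from `to` along parent links reversed
  # (i.e. there is a directed path to -> ... -> from)
  stack <- to
  seen <- logical(length(parents))
  while (length(stack)) {
    u <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (u == from) return(TRUE)
    if (seen[u]) next
    seen[u] <- TRUE
    # children of u
    for (j in seq_along(parents)) {
      pa <- parents[[j]]
      if (!is.null(drop) && u == drop[1] && j == drop[2]) pa <- setdiff(pa, u)
      if (u %in% pa) stack <- c(stack, j)
    }
  }
  FALSE
}

random_dag <- function(v, max_parents = Inf, p_edge = 0.25) {
  ord <- sample.int(v)
  parents <- replicate(v, integer(0), simplify = FALSE)
  for (a in seq_len(v - 1)) for (b in (a + 1):v) {
    if (runif(1) < p_edge &&
        length(parents[[ord[b]]]) < max_parents)
      parents[[ord[b]]] <- c(parents[[ord[b]]], ord[a])
  }
  parents
}

#' Format an arc strength as an exponentiated Bayes factor
#'
#' Converts a natural-log arc strength to `a x 10^b` scientific notation
#' with a three-significant-figure mantissa, via base-10 exponent
#' decomposition (`b = floor(arc / ln 10)`) so that values far beyond
#' double overflow are still exact.
#'
#' @param arc finite arc strength in natural-log units.
#' @return string such as `"3.01x10^127"`.
#' @export
format_exp_arc <- function(arc) {
  if (!is.finite(arc)) stop("arc must be finite")
  b <- floor(arc / log(10))
  m <- 10^(arc / log(10) - b)
  m <- signif(m, 3)
  if (m >= 10) { m <- m / 10; b <- b + 1 }
  sprintf("%.2fx10^%d", m, b)
}

#' Numeric value of an exponentiated arc strength
#'
#' `exp(arc)` computed through the same base-10 decomposition and
#' 3-significant-figure rounding as [format_exp_arc()]; returns `Inf`
#' when the value exceeds double range.
#'
#' @param arc finite arc strength in natural-log units.
#' @return numeric Bayes factor.
#' @export
exp_arc_value <- function(arc) {
  b <- floor(arc / log(10))
  m <- signif(10^(arc / log(10) - b), 3)
  if (m >= 10) { m <- m / 10; b <- b + 1 }
  m * 10^b
}
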