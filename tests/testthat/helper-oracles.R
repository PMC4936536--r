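# Independent oracles and fixture builders shared across the test files.

# breadth-first connected components, independent of the package's igraph path
bfs_components <- function(nb) {
  ids <- names(nb)
  comp <- stats::setNames(rep(0L, length(ids)), ids)
  k <- 0L
  for (s in ids) {
    if (comp[[s]] > 0L) next
    k <- k + 1L
    queue <- s
    while (length(queue)) {
      u <- queue[[1L]]; queue <- queue[-1L]
      if (comp[[u]] > 0L) next
      comp[[u]] <- k
      queue <- c(queue, setdiff(nb[[u]], names(comp)[comp > 0L]))
    }
  }
  comp
}

# random symmetric irreflexive graph on n labelled nodes
random_sym_graph <- function(n, p = 0.3, ids = sprintf("u%02d", seq_len(n))) {
  nb <- stats::setNames(rep(list(character(0)), n), ids)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      if (stats::runif(1) < p) {
        nb[[i]] <- c(nb[[i]], ids[j])
        nb[[j]] <- c(nb[[j]], ids[i])
      }
    }
  }
  nb
}

# enumerate every labelled graph on n nodes (n small)
all_graphs <- function(n) {
  ids <- letters[seq_len(n)]
  pairs <- utils::combn(n, 2)
  m <- ncol(pairs)
  lapply(seq_len(2^m) - 1L, function(mask) {
    nb <- stats::setNames(rep(list(character(0)), n), ids)
    for (e in seq_len(m)) {
      if (bitwAnd(mask, bitwShiftL(1L, e - 1L)) != 0L) {
        i <- pairs[1, e]; j <- pairs[2, e]
        nb[[i]] <- c(nb[[i]], ids[j])
        nb[[j]] <- c(nb[[j]], ids[i])
      }
    }
    nb
  })
}

# dense graph Laplacian from a neighbour list
graph_laplacian <- function(nb) {
  ids <- names(nb)
  W <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in ids) W[i, nb[[i]]] <- 1
  diag(rowSums(W)) - W
}

# conditional (mean, variance) of v_i derived from the joint icar_logpdf,
# exact for a quadratic log density
cond_from_joint <- function(i, v, adj, sigma) {
  f <- function(t) {
    vv <- v; vv[i] <- t
    icar_logpdf(vv, adj, sigma)
  }
  a <- (f(1) + f(-1) - 2 * f(0)) / 2
  b <- (f(1) - f(-1)) / 2
  list(mean = -b / (2 * a), variance = -1 / (2 * a))
}

# 6 fine units in 2 coarse units, hand-checkable
tiny_geog <- function() {
  fine <- list(a = c("b", "d"), b = c("a", "c"), c = c("b", "f"),
               d = c("a", "e"), e = c("d", "f"), f = c("c", "e"))
  coarse <- list(X = "Y", Y = "X")
  multiscale_geography(fine, coarse,
                       c(a = "X", b = "X", c = "X",
                         d = "Y", e = "Y", f = "Y"))
}

tiny_dataset <- function(geog, y = c(3, 5, 2, 7, 4, 6),
                         n = c(30, 40, 25, 50, 35, 45),
                         x = c(1, 2, 3, 4, 5, 6.5)) {
  multiscale_dataset(
    data.frame(unit_id = geog$fine_ids, y = y, n = n, x = x,
               stringsAsFactors = FALSE), geog)
}

# 2 fine units in 2 coarse units: the grid-oracle toy
toy_geog <- function() {
  multiscale_geography(list(a = "b", b = "a"), list(D1 = "D2", D2 = "D1"),
                       c(a = "D1", b = "D2"))
}

toy_dataset <- function(y = c(13, 21), n = c(60, 80)) {
  g <- toy_geog()
  multiscale_dataset(
    data.frame(unit_id = g$fine_ids, y = y, n = n, x = c(-1, 1),
               stringsAsFactors = FALSE), g)
}

# posterior_samples object built from an explicit draw matrix (one chain),
# for oracle tests of summaries / DIC / MSPE
manual_samples <- function(draws, geog, spec, dev1 = NULL, dev2 = NULL,
                           std = NULL) {
  colnames(draws) <- multiscaleCAR:::param_names(geog)
  multiscaleCAR:::new_posterior_samples(
    chains = list(draws),
    deviance = list(list(level1 = dev1, level2 = dev2)),
    config = mcmc_config(n_chains = 1, n_iter = nrow(draws), burn_in = 0,
                         seed = 1),
    spec = spec,
    geog_info = list(n_fine = length(geog$fine_ids),
                     n_coarse = length(geog$coarse_ids),
                     fine_ids = geog$fine_ids,
                     coarse_ids = geog$coarse_ids),
    acceptance = list(),
    data_std = std)
}

# draw-matrix row for a constant parameter state
state_row <- function(state) {
  c(state$beta01, state$beta02, state$beta11, state$beta12,
    state$sigma_v1, state$sigma_v2, state$sigma_eps1, state$sigma_eps2,
    state$v1, state$v2, state$eps1, state$eps2)
}

# the desk-scale recovery experiment is shared by several acceptance tests;
# run it once per test session
recovery_cache <- new.env(parent = emptyenv())
cached_recovery <- function() {
  if (is.null(recovery_cache$report)) {
    recovery_cache$report <- recovery_experiment(n_replicates = 20, seed = 20260901)
  }
  recovery_cache$report
}
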