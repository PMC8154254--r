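# Optimal-pathway search.  The pathway maximizing the product of edge decay
# factors is the shortest path under edge weight -ln(q); all weights are
# non-negative because q is clamped at its kind's prefactor A, so Dijkstra's
# algorithm applies.  Ties in total weight are broken toward fewer atoms,
# then toward the lexicographically smallest sequence of atom serials, so
# output is deterministic across runs and platforms.

# adjacency with per-edge payload, both directions
weighted_adjacency <- function(graph, params, drop_fe_his = FALSE) {
  e <- graph$edges
  if (drop_fe_his && any(e$fe_his)) e <- e[!e$fe_his, , drop = FALSE]
  w <- if (nrow(e) > 0) edge_weights(e, params) else numeric(0)
  q <- if (nrow(e) > 0) edge_decay(e$r, e$kind, params) else numeric(0)
  from <- c(e$i, e$j); to <- c(e$j, e$i)
  ord <- order(from, to)
  from <- from[ord]; to <- to[ord]
  payload <- list(to = to, w = c(w, w)[ord], q = c(q, q)[ord],
                  kind = c(e$kind, e$kind)[ord],
                  fe_his = c(e$fe_his, e$fe_his)[ord])
  starts <- c(1L, 1L + cumsum(tabulate(from, nbins = graph$n_atoms)))
  list(payload = payload, starts = starts, counts =
         tabulate(from, nbins = graph$n_atoms))
}

neighbors_of <- function(adj, u) {
  cnt <- adj$counts[u]
  if (cnt == 0L) return(NULL)
  idx <- seq.int(adj$starts[u], length.out = cnt)
  lapply(adj$payload, `[`, idx)
}

path_result <- function(graph, chain, params) {
  serials <- graph$structure$atoms$serial
  if (length(chain) == 0) {
    return(structure(list(atoms = integer(0), serials = integer(0),
                          edge_decays = numeric(0), ln_k = -Inf,
                          atom_count = NA_integer_,
                          kind_counts = c(covalent = 0L, hbond = 0L,
                                          space = 0L),
                          uses_fe_his = FALSE, reachable = FALSE),
                     class = "et_path"))
  }
  e <- graph$edges
  key <- paste(e$i, e$j)
  lookup <- stats::setNames(seq_len(nrow(e)), key)
  qs <- numeric(length(chain) - 1)
  kinds <- character(length(chain) - 1)
  fe <- FALSE
  if (length(chain) > 1) {
    for (k in seq_len(length(chain) - 1)) {
      a <- min(chain[k], chain[k + 1]); b <- max(chain[k], chain[k + 1])
      row <- lookup[[paste(a, b)]]
      if (is.null(row)) stop("path step ", k, " is not a graph edge")
      qs[k] <- edge_decay(e$r[row], e$kind[row], params)
      kinds[k] <- e$kind[row]
      fe <- fe || e$fe_his[row]
    }
  }
  structure(list(
    atoms = as.integer(chain),
    serials = serials[chain],
    edge_decays = qs,
    ln_k = if (length(qs)) sum(log(qs)) else 0,
    atom_count = length(chain),
    kind_counts = c(covalent = sum(kinds == "covalent"),
                    hbond = sum(kinds == "hbond"),
                    space = sum(kinds == "space")),
    uses_fe_his = fe,
    reachable = TRUE), class = "et_path")
}

#' @export
print.et_path <- function(x, ...) {
  if (!x$reachable) { cat("et_path: unreachable (ln_k = -Inf)\n"); return(invisible(x)) }
  cat("et_path: ln(k) =", format(x$ln_k, digits = 6), "over",
      x$atom_count, "atoms (",
      paste(names(x$kind_counts), x$kind_counts, sep = "=", collapse = ", "),
      ")\n")
  invisible(x)
}

# lexicographic comparison of serial sequences; TRUE if a < b
lex_less <- function(a, b) {
  n <- min(length(a), length(b))
  if (n > 0) {
    d <- which(a[seq_len(n)] != b[seq_len(n)])
    if (length(d) > 0) return(a[d[1]] < b[d[1]])
  }
  length(a) < length(b)
}

#' Best electron-transfer pathway between two atoms
#'
#' Finds the donor-to-acceptor path maximizing the product of edge decay
#' factors with Dijkstra's algorithm on `-ln(q)` edge weights.  Ties on
#' total weight are resolved toward fewer atoms, then toward the
#' lexicographically smallest atom-serial sequence.
#'
#' @param graph an `et_graph` from [build_transfer_graph()]
#' @param donor,acceptor atom index or selector list (see [select_atoms()])
#' @param params [decay_parameters()]
#' @param forbid_fe_his exclude the heme-iron/proximal-histidine link from
#'   the graph before searching (the link is an artificial construct; paths
#'   through it can instead be flagged via `uses_fe_his`)
#' @return an `et_path`: atom chain, per-edge decays, `ln_k` (sum of log
#'   decay factors, <= 0), atom count and per-kind edge counts.  An
#'   unreachable acceptor yields a sentinel with `ln_k = -Inf`.
#' @export
best_path <- function(graph, donor, acceptor, params = decay_parameters(),
                      forbid_fe_his = FALSE) {
  donor <- resolve_node(graph, donor)
  acceptor <- resolve_node(graph, acceptor)
  n <- graph$n_atoms
  if (donor == acceptor) return(path_result(graph, donor, params))
  adj <- weighted_adjacency(graph, params, drop_fe_his = forbid_fe_his)
  serial <- graph$structure$atoms$serial
  dist <- rep(Inf, n); hops <- rep(Inf, n)
  parent <- rep(NA_integer_, n)
  visited <- rep(FALSE, n)
  dist[donor] <- 0; hops[donor] <- 0
  path_to <- function(v) {
    p <- v
    while (!is.na(parent[p[1]])) p <- c(parent[p[1]], p)
    p
  }
  repeat {
    cand <- which(!visited & is.finite(dist))
    if (length(cand) == 0) break
    dmin <- min(dist[cand])
    u_set <- cand[dist[cand] == dmin]
    if (length(u_set) > 1) {
      hmin <- min(hops[u_set])
      u_set <- u_set[hops[u_set] == hmin]
      if (length(u_set) > 1) {
        best <- u_set[1]; bestp <- serial[path_to(best)]
        for (v in u_set[-1]) {
          pv <- serial[path_to(v)]
          if (lex_less(pv, bestp)) { best <- v; bestp <- pv }
        }
        u_set <- best
      }
    }
    u <- u_set[1]
    if (u == acceptor) break
    visited[u] <- TRUE
    nb <- neighbors_of(adj, u)
    if (is.null(nb)) next
    for (k in seq_along(nb$to)) {
      v <- nb$to[k]
      if (visited[v]) next
      nd <- dist[u] + nb$w[k]
      nh <- hops[u] + 1
      take <- FALSE
      if (nd < dist[v]) take <- TRUE
      else if (nd == dist[v]) {
        if (nh < hops[v]) take <- TRUE
        else if (nh == hops[v] && !is.na(parent[v])) {
          cand_path <- serial[c(path_to(u), v)]
          take <- lex_less(cand_path, serial[path_to(v)])
        }
      }
      if (take) { dist[v] <- nd; hops[v] <- nh; parent[v] <- u }
    }
  }
  if (!is.finite(dist[acceptor])) return(path_result(graph, integer(0), params))
  path_result(graph, path_to(acceptor), params)
}

resolve_node <- function(graph, node) {
  if (is.list(node)) return(select_one_atom(graph$structure, node))
  node <- as.integer(node)
  if (length(node) != 1L || node < 1L || node > graph$n_atoms)
    stop("node index out of range")
  node
}

#' Exhaustive-path oracle for [best_path()]
#'
#' Enumerates every simple donor-to-acceptor path (depth-first) and returns
#' the best under the same composite order as [best_path()]: maximal product
#' of decays, then fewest atoms, then lexicographically smallest serials.
#' Intended as an independent correctness oracle for small graphs.
#'
#' @inheritParams best_path
#' @param max_nodes refuse graphs larger than this (enumeration guard)
#' @return an `et_path`
#' @export
brute_force_best_path <- function(graph, donor, acceptor,
                                  params = decay_parameters(),
                                  forbid_fe_his = FALSE, max_nodes = 14L) {
  if (graph$n_atoms > max_nodes)
    stop("graph has ", graph$n_atoms, " nodes; enumeration guard is ",
         max_nodes)
  donor <- resolve_node(graph, donor)
  acceptor <- resolve_node(graph, acceptor)
  if (donor == acceptor) return(path_result(graph, donor, params))
  adj <- weighted_adjacency(graph, params, drop_fe_his = forbid_fe_his)
  serial <- graph$structure$atoms$serial
  best <- NULL; best_w <- Inf; best_len <- Inf; best_ser <- NULL
  visit <- function(u, path, w) {
    nb <- neighbors_of(adj, u)
    if (is.null(nb)) return()
    for (k in seq_along(nb$to)) {
      v <- nb$to[k]
      if (v %in% path) next
      nw <- w + nb$w[k]
      npath <- c(path, v)
      if (v == acceptor) {
        nser <- serial[npath]
        better <- nw < best_w ||
          (nw == best_w && (length(npath) < best_len ||
             (length(npath) == best_len && lex_less(nser, best_ser))))
        if (better) {
          best <<- npath; best_w <<- nw; best_len <<- length(npath)
          best_ser <<- nser
        }
      } else {
        visit(v, npath, nw)
      }
    }
  }
  visit(donor, donor, 0)
  if (is.null(best)) return(path_result(graph, integer(0), params))
  path_result(graph, best, params)
}
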