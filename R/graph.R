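# Typed atom-graph construction: covalent bond perception (residue templates
# + distance fallback), geometric hydrogen-bond detection, and through-space
# edges within a cutoff.

# All atom pairs with r <= cutoff, computed blockwise so large structures
# never materialize a full n x n distance matrix.
pairs_within <- function(xyz, cutoff, block = 600L) {
  n <- nrow(xyz)
  if (n < 2L) return(data.frame(i = integer(0), j = integer(0),
                                r = numeric(0)))
  cut2 <- cutoff^2
  sq <- rowSums(xyz^2)
  starts <- seq(1L, n, by = block)
  acc <- vector("list", 0)
  for (bi in starts) {
    ri <- bi:min(bi + block - 1L, n)
    for (bj in starts[starts >= bi]) {
      rj <- bj:min(bj + block - 1L, n)
      d2 <- outer(sq[ri], sq[rj], "+") - 2 * tcrossprod(xyz[ri, , drop = FALSE],
                                                        xyz[rj, , drop = FALSE])
      hit <- which(d2 <= cut2, arr.ind = TRUE)
      if (nrow(hit) == 0) next
      ii <- ri[hit[, 1]]
      jj <- rj[hit[, 2]]
      keep <- ii < jj
      if (!any(keep)) next
      acc[[length(acc) + 1L]] <- data.frame(
        i = ii[keep], j = jj[keep],
        r = sqrt(pmax(d2[hit][keep], 0)))
    }
  }
  if (length(acc) == 0) return(data.frame(i = integer(0), j = integer(0),
                                          r = numeric(0)))
  do.call(rbind, acc)
}

edge_frame <- function(i, j, kind, r, fe_his = FALSE) {
  swap <- i > j
  tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  df <- data.frame(i = as.integer(i), j = as.integer(j), kind = kind,
                   r = as.numeric(r),
                   fe_his = rep_len(fe_his, length(i)),
                   stringsAsFactors = FALSE)
  df[!duplicated(paste(df$i, df$j)), , drop = FALSE]
}

dist_ij <- function(xyz, i, j) {
  sqrt(rowSums((xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE])^2))
}

#' Perceive covalent bonds of a structure
#'
#' Intra-residue bonds come from heavy-atom templates for the 20 standard
#' residues, heme b (HEM) and water; atoms a template does not name
#' (hydrogens, nonstandard atoms) and residues without a template fall back
#' to the distance rule `r <= r_cov(i) + r_cov(j) + 0.45` Angstrom.  Peptide
#' bonds are added between backbone C and N atoms within 2 Angstrom, and the
#' heme iron is linked to the proximal histidine NE2 within 3 Angstrom (the
#' coordination bond treated as covalent; flagged `fe_his`).
#'
#' @param structure an [et_structure()] (first model is used)
#' @return data.frame of covalent edges with columns `i`, `j`, `kind`,
#'   `r` (Angstrom), `fe_his`
#' @export
perceive_covalent_bonds <- function(structure) {
  a <- structure$atoms
  xyz <- model_xyz(structure, 1L)
  n <- nrow(a)
  res_key <- paste(a$chain, a$resno, a$resname)
  groups <- split(seq_len(n), res_key)
  ei <- integer(0); ej <- integer(0)
  warned <- character(0)
  for (idx in groups) {
    resname <- a$resname[idx[1]]
    tmpl <- residue_template(resname)
    covered <- character(0)
    if (!is.null(tmpl) && nrow(tmpl) > 0) {
      covered <- unique(as.vector(tmpl))
      name_to_idx <- split(idx, a$name[idx])
      for (k in seq_len(nrow(tmpl))) {
        p <- name_to_idx[[tmpl[k, 1]]]
        q <- name_to_idx[[tmpl[k, 2]]]
        if (length(p) == 1L && length(q) == 1L &&
            dist_ij(xyz, p, q) <= 3.0) {
          ei <- c(ei, p); ej <- c(ej, q)
        }
      }
    } else if (is.null(tmpl)) {
      if (!(resname %in% warned)) {
        warning("no bond template for residue ", resname,
                "; using the covalent distance rule", call. = FALSE)
        warned <- c(warned, resname)
      }
    }
    # distance rule for template-missing atoms (and whole unknown residues)
    loose <- idx[!(a$name[idx] %in% covered)]
    if (length(loose) > 0 && length(idx) > 1) {
      for (p in loose) {
        others <- setdiff(idx, p)
        rr <- dist_ij(xyz, rep(p, length(others)), others)
        thr <- covalent_radius(a$element[p]) +
          covalent_radius(a$element[others]) + 0.45
        hit <- others[rr <= thr & rr > 0]
        if (length(hit) > 0) { ei <- c(ei, rep(p, length(hit))); ej <- c(ej, hit) }
      }
    }
  }
  # peptide bonds: backbone C to backbone N of another residue within 2.0 A
  cs <- which(a$name == "C" & !a$het)
  ns <- which(a$name == "N" & !a$het)
  if (length(cs) > 0 && length(ns) > 0) {
    for (p in cs) {
      rr <- dist_ij(xyz, rep(p, length(ns)), ns)
      hit <- ns[rr <= 2.0 & res_key[ns] != res_key[p]]
      if (length(hit) > 0) { ei <- c(ei, rep(p, length(hit))); ej <- c(ej, hit) }
    }
  }
  # disulfides
  sg <- which(a$name == "SG")
  if (length(sg) > 1) {
    pr <- pairs_within(xyz[sg, , drop = FALSE], 2.55)
    if (nrow(pr) > 0) { ei <- c(ei, sg[pr$i]); ej <- c(ej, sg[pr$j]) }
  }
  fe_flag <- rep(FALSE, length(ei))
  # heme iron -- proximal histidine NE2 coordination link
  fe <- which(a$resname == "HEM" & toupper(a$name) == "FE")
  ne2 <- which(a$resname == "HIS" & a$name == "NE2")
  for (f in fe) {
    if (length(ne2) == 0) { warning("heme present but no His NE2 found; ",
                                    "Fe-His link not added", call. = FALSE); break }
    rr <- dist_ij(xyz, rep(f, length(ne2)), ne2)
    if (min(rr) <= 3.0) {
      ei <- c(ei, f); ej <- c(ej, ne2[which.min(rr)]); fe_flag <- c(fe_flag, TRUE)
    } else {
      warning("no His NE2 within 3 Angstrom of heme Fe; link not added",
              call. = FALSE)
    }
  }
  if (length(ei) == 0)
    return(data.frame(i = integer(0), j = integer(0), kind = character(0),
                      r = numeric(0), fe_his = logical(0)))
  edge_frame(ei, ej, "covalent", dist_ij(xyz, ei, ej), fe_flag)
}

#' Hydrogen-bond detection criteria
#'
#' With hydrogens present the geometric rule is the one used for trajectory
#' analysis here: hydrogen-acceptor distance below `max_ha_distance` (2.5
#' Angstrom = 0.25 nm) and donor-H-acceptor angle above `min_dha_angle`
#' (135 degrees).  Structures without polar hydrogens (crystal structures)
#' use the donor-acceptor heavy-atom distance `heavy_atom_fallback_distance`
#' instead.
#'
#' @param max_ha_distance Angstrom, H...acceptor cutoff
#' @param min_dha_angle degrees, donor-H...acceptor angle threshold
#' @param heavy_atom_fallback_distance Angstrom, donor...acceptor cutoff
#'   when no hydrogens are present
#' @return object of class `et_hbond_criteria`
#' @export
hbond_criteria <- function(max_ha_distance = 2.5, min_dha_angle = 135,
                           heavy_atom_fallback_distance = 3.5) {
  stopifnot(max_ha_distance > 0, heavy_atom_fallback_distance > 0,
            min_dha_angle > 0, min_dha_angle <= 180)
  structure(list(max_ha_distance = max_ha_distance,
                 min_dha_angle = min_dha_angle,
                 heavy_atom_fallback_distance = heavy_atom_fallback_distance),
            class = "et_hbond_criteria")
}

adjacency_list <- function(edges, n) {
  adj <- vector("list", n)
  if (nrow(edges) == 0) return(adj)
  both_from <- c(edges$i, edges$j)
  both_to <- c(edges$j, edges$i)
  sp <- split(both_to, factor(both_from, levels = seq_len(n)))
  lapply(sp, as.integer)
}

# atoms within `hops` covalent bonds of each seed atom (including the seed)
within_bond_hops <- function(adj, seed, hops = 2L) {
  seen <- seed
  frontier <- seed
  for (k in seq_len(hops)) {
    frontier <- unique(unlist(adj[frontier]))
    frontier <- setdiff(frontier, seen)
    if (length(frontier) == 0) break
    seen <- c(seen, frontier)
  }
  seen
}

angle_at <- function(xyz, a, b, c) {
  v1 <- xyz[a, ] - xyz[b, ]
  v2 <- xyz[c, ] - xyz[b, ]
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Detect hydrogen-bond edges
#'
#' Donors and acceptors are N/O atoms.  When the structure carries polar
#' hydrogens the criterion is H...A distance plus D-H...A angle; otherwise a
#' heavy-atom donor-acceptor distance cutoff is applied to N/O pairs not
#' connected by a covalent path of one or two bonds.  The edge length
#' `r` is always the donor-acceptor heavy-atom distance (the quantity the
#' tunneling decay law is parameterized on).
#'
#' @param structure an [et_structure()] (first model used)
#' @param criteria an [hbond_criteria()] object
#' @param covalent covalent edge table from [perceive_covalent_bonds()];
#'   recomputed when omitted
#' @param xyz optional replacement coordinate matrix (used for per-frame
#'   re-detection on trajectories)
#' @return data.frame of hbond edges (`i`, `j`, `kind`, `r`, `fe_his`)
#' @export
detect_hbond_edges <- function(structure, criteria = hbond_criteria(),
                               covalent = NULL, xyz = NULL) {
  a <- structure$atoms
  if (is.null(xyz)) xyz <- model_xyz(structure, 1L)
  if (is.null(covalent)) covalent <- perceive_covalent_bonds(structure)
  n <- nrow(a)
  adj <- adjacency_list(covalent, n)
  is_no <- a$element %in% c("N", "O")
  is_h <- a$element == "H"
  no_idx <- which(is_no)
  empty <- data.frame(i = integer(0), j = integer(0), kind = character(0),
                      r = numeric(0), fe_his = logical(0))
  if (length(no_idx) < 2) return(empty)
  # polar hydrogens: H atoms covalently attached to an N/O
  h_parent <- rep(NA_integer_, n)
  for (h in which(is_h)) {
    nb <- adj[[h]]
    nb <- nb[is_no[nb]]
    if (length(nb) > 0) h_parent[h] <- nb[1]
  }
  polar_h <- which(!is.na(h_parent))
  ei <- integer(0); ej <- integer(0)
  if (length(polar_h) > 0) {
    # hydrogen-based criterion
    for (h in polar_h) {
      d <- h_parent[h]
      rr <- dist_ij(xyz, rep(h, length(no_idx)), no_idx)
      cand <- no_idx[rr < criteria$max_ha_distance]
      cand <- setdiff(cand, c(d, adj[[h]], adj[[d]]))
      for (acc in cand) {
        if (angle_at(xyz, d, h, acc) > criteria$min_dha_angle) {
          ei <- c(ei, d); ej <- c(ej, acc)
        }
      }
    }
  } else {
    # heavy-atom fallback for hydrogen-free structures
    pr <- pairs_within(xyz[no_idx, , drop = FALSE],
                       criteria$heavy_atom_fallback_distance)
    if (nrow(pr) > 0) {
      for (k in seq_len(nrow(pr))) {
        d <- no_idx[pr$i[k]]; acc <- no_idx[pr$j[k]]
        if (!(acc %in% within_bond_hops(adj, d, 2L))) {
          ei <- c(ei, d); ej <- c(ej, acc)
        }
      }
    }
  }
  if (length(ei) == 0) return(empty)
  edge_frame(ei, ej, "hbond", dist_ij(xyz, ei, ej))
}

#' Assemble the electron-transfer graph
#'
#' Combines covalent and hydrogen-bond edges with through-space edges for
#' every remaining atom pair within `space_cutoff`.  Each atom pair carries
#' at most one edge, with precedence covalent > hbond > space.
#'
#' @param structure an [et_structure()]
#' @param covalent,hbond edge tables (computed when omitted)
#' @param space_cutoff Angstrom; pairs farther apart get no space edge.
#'   Beyond the 6 Angstrom default a through-space jump is attenuated by
#'   more than e^-7.8 relative to contact and cannot occur on an optimal
#'   path.
#' @param criteria [hbond_criteria()] used when `hbond` is omitted
#' @param xyz optional replacement coordinates (per-frame rebuilds)
#' @return object of class `et_graph`: `structure`, `edges`, `space_cutoff`
#' @export
build_transfer_graph <- function(structure, covalent = NULL, hbond = NULL,
                                 space_cutoff = 6.0,
                                 criteria = hbond_criteria(), xyz = NULL) {
  stopifnot(space_cutoff > 0)
  if (nrow(structure$atoms) == 0) stop("empty structure")
  if (is.null(xyz)) xyz <- model_xyz(structure, 1L)
  if (is.null(covalent)) covalent <- perceive_covalent_bonds(structure)
  if (is.null(hbond)) hbond <- detect_hbond_edges(structure, criteria,
                                                  covalent, xyz)
  n <- nrow(structure$atoms)
  pr <- pairs_within(xyz, space_cutoff)
  taken <- c(paste(covalent$i, covalent$j), paste(hbond$i, hbond$j))
  free <- !(paste(pr$i, pr$j) %in% taken)
  space <- if (any(free)) edge_frame(pr$i[free], pr$j[free], "space",
                                     pr$r[free])
           else data.frame(i = integer(0), j = integer(0),
                           kind = character(0), r = numeric(0),
                           fe_his = logical(0))
  edges <- rbind(covalent, hbond, space)
  rownames(edges) <- NULL
  structure(list(structure = structure, edges = edges,
                 space_cutoff = space_cutoff, n_atoms = n),
            class = "et_graph")
}

#' @export
print.et_graph <- function(x, ...) {
  tab <- table(x$edges$kind)
  cat("et_graph:", x$n_atoms, "atoms,", nrow(x$edges), "edges (",
      paste(names(tab), tab, sep = "=", collapse = ", "), ")\n")
  invisible(x)
}

#' One-call graph construction from a structure
#' @inheritParams build_transfer_graph
#' @return an `et_graph`
#' @export
transfer_graph <- function(structure, criteria = hbond_criteria(),
                           space_cutoff = 6.0) {
  cov <- perceive_covalent_bonds(structure)
  hb <- detect_hbond_edges(structure, criteria, cov)
  build_transfer_graph(structure, cov, hb, space_cutoff, criteria)
}

#' Export graph edges as TSV (atom_i, atom_j, kind, r)
#' @param graph an `et_graph`
#' @param path destination file
#' @return `path`, invisibly
#' @export
export_graph <- function(graph, path) {
  e <- graph$edges
  lab <- atom_labels(graph$structure)
  out <- data.frame(atom_i = lab[e$i], atom_j = lab[e$j],
                    kind = e$kind, r = e$r)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
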