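## Bond-graph utilities: connectivity, topological separations, ring
## perception, rotatable-bond detection. Graph algorithms go through igraph.

.bond_graph <- function(mol, drop = NULL) {
  bd <- mol@bonds
  if (!is.null(drop) && nrow(bd) > 0) {
    key <- paste(pmin(bd$i, bd$j), pmax(bd$i, bd$j))
    dk <- paste(pmin(drop[, 1], drop[, 2]), pmax(drop[, 1], drop[, 2]))
    bd <- bd[!key %in% dk, , drop = FALSE]
  }
  igraph::graph_from_edgelist(cbind(bd$i, bd$j), directed = FALSE) |>
    igraph::add_vertices(nv = max(0L, nrow(mol@atoms) -
      max(c(0L, bd$i, bd$j))))
}

## Topological bond separation matrix (1 = bonded, 2 = 1-3, ...).
.bond_separation <- function(mol) {
  g <- .bond_graph(mol)
  igraph::distances(g)
}

## Cycle basis of the bond graph: list of bond index vectors, one per
## independent cycle. Uses the non-tree edges of a spanning forest; each
## non-tree edge closes exactly one fundamental cycle.
.ring_bonds <- function(mol) {
  bd <- mol@bonds
  if (nrow(bd) == 0) return(list())
  n <- nrow(mol@atoms)
  ## union-find over edges: edges joining already-connected atoms close cycles
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  cyc_edges <- integer(0)
  for (e in seq_len(nrow(bd))) {
    a <- find(bd$i[e]); b <- find(bd$j[e])
    if (a == b) cyc_edges <- c(cyc_edges, e) else parent[a] <- b
  }
  if (length(cyc_edges) == 0) return(list())
  ## for each cycle-closing edge, the cycle = that edge + tree path
  tree_g <- igraph::graph_from_edgelist(
    cbind(bd$i[-cyc_edges], bd$j[-cyc_edges]), directed = FALSE)
  if (igraph::vcount(tree_g) < n)
    tree_g <- igraph::add_vertices(tree_g, n - igraph::vcount(tree_g))
  lapply(cyc_edges, function(e) {
    p <- igraph::shortest_paths(tree_g, bd$i[e], bd$j[e])$vpath[[1]]
    p <- as.integer(p)
    ## bond indices along the path plus the closing edge
    key <- paste(pmin(bd$i, bd$j), pmax(bd$i, bd$j))
    path_keys <- paste(pmin(p[-length(p)], p[-1]), pmax(p[-length(p)], p[-1]))
    c(match(path_keys, key), e)
  })
}

## Atoms that are members of at least one ring.
.ring_atoms <- function(mol) {
  rb <- .ring_bonds(mol)
  if (length(rb) == 0) return(integer(0))
  bd <- mol@bonds
  sort(unique(unlist(lapply(rb, function(e) c(bd$i[e], bd$j[e])))))
}

## Counts used as hold-out stratification features: number of independent
## cycles and the member count of the largest ring in the cycle basis.
.ring_stats <- function(mol) {
  rb <- .ring_bonds(mol)
  list(n_cycle = length(rb),
       n_ring = if (length(rb)) max(vapply(rb, length, 1L)) else 0L)
}

## Heavy-atom neighbor count per atom.
.heavy_degree <- function(mol) {
  n <- nrow(mol@atoms)
  deg <- integer(n)
  heavy <- mol@atoms$element != "H"
  for (e in seq_len(nrow(mol@bonds))) {
    i <- mol@bonds$i[e]; j <- mol@bonds$j[e]
    if (heavy[j]) deg[i] <- deg[i] + 1L
    if (heavy[i]) deg[j] <- deg[j] + 1L
  }
  deg
}

## Rotatable bonds for conformer sampling on a (possibly ring-opened) graph:
## single non-aromatic, non-amide bonds, acyclic in the working graph, with
## at least one heavy neighbor beyond the bond on both sides (rotations of
## H-only tops are invisible to heavy-atom RMSD and are skipped).
.sampling_dihedrals <- function(mol, opened_drop = NULL) {
  bd <- mol@bonds
  if (nrow(bd) == 0) return(integer(0))
  keep_ring <- .ring_bond_flags(mol, opened_drop)
  hdeg <- .heavy_degree(mol)
  heavy <- mol@atoms$element != "H"
  ok <- bd$order == "1" & !keep_ring &
    heavy[bd$i] & heavy[bd$j] &
    (hdeg[bd$i] - as.integer(heavy[bd$j])) >= 1L &
    (hdeg[bd$j] - as.integer(heavy[bd$i])) >= 1L
  which(ok)
}

## Flags bonds that remain in a ring of the working graph (after removing
## `drop`, an m x 2 matrix of opened bonds).
.ring_bond_flags <- function(mol, drop = NULL) {
  bd <- mol@bonds
  flag <- logical(nrow(bd))
  if (nrow(bd) == 0) return(flag)
  key <- paste(pmin(bd$i, bd$j), pmax(bd$i, bd$j))
  keep <- rep(TRUE, nrow(bd))
  if (!is.null(drop)) {
    dk <- paste(pmin(drop[, 1], drop[, 2]), pmax(drop[, 1], drop[, 2]))
    keep <- !key %in% dk
  }
  sub <- bd[keep, , drop = FALSE]
  if (nrow(sub) == 0) return(flag)
  mol2 <- mol
  mol2@bonds <- sub
  rb <- .ring_bonds(mol2)
  if (length(rb) == 0) return(flag)
  sub_key <- paste(pmin(sub$i, sub$j), pmax(sub$i, sub$j))
  ring_key <- unique(unlist(lapply(rb, function(e) sub_key[e])))
  flag[key %in% ring_key] <- TRUE
  flag
}

#' Count rotatable bonds
#'
#' Standard rotatable-bond count: acyclic single bonds between two
#' non-terminal heavy atoms, excluding amide C-N bonds.
#'
#' @param mol a \code{Molecule}.
#' @return integer count.
#' @export
countRotatableBonds <- function(mol) {
  bd <- mol@bonds
  if (nrow(bd) == 0) return(0L)
  in_ring <- .ring_bond_flags(mol)
  heavy <- mol@atoms$element != "H"
  hdeg <- .heavy_degree(mol)
  ok <- bd$order == "1" & !in_ring &
    heavy[bd$i] & heavy[bd$j] &
    (hdeg[bd$i] - 1L) >= 1L & (hdeg[bd$j] - 1L) >= 1L
  sum(ok)
}
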