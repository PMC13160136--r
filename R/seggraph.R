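# Supervoxel generation, region adjacency graph with hierarchical
# agglomeration merge scores, and chunked-graph ("graphene") export for
# collaborative proofreading.
#
# Conventions:
#  * affinity volumes are (3, z, y, x); channel 1/2/3 holds the affinity
#    between voxel v and its +z/+y/+x face neighbor, 0 toward the outside;
#  * merge scores live in [0, 1], low = likely same object; exported edge
#    affinity = 1 - merge score;
#  * all algorithms are deterministic: ties are broken by lexicographic
#    (z, y, x) voxel order, cluster merges by smallest cluster ids.

# ---- small utilities ---------------------------------------------------

# linear index <-> (z, y, x); R arrays are column-major so z varies fastest
vox_lin <- function(z, y, x, d) z + d[1] * ((y - 1) + d[2] * (x - 1))

vox_zyx <- function(lin, d) {
  lin0 <- lin - 1
  z <- lin0 %% d[1]
  y <- (lin0 %/% d[1]) %% d[2]
  x <- lin0 %/% (d[1] * d[2])
  cbind(z = z + 1, y = y + 1, x = x + 1)
}

# lexicographic (z, y, x) sort key
vox_key <- function(lin, d) {
  p <- vox_zyx(lin, d)
  ((p[, 1] - 1) * d[2] + (p[, 2] - 1)) * d[3] + (p[, 3] - 1)
}

# All face-adjacent voxel pairs as linear indices with their affinities:
# data.frame(a, b, aff) where a is the anchor (channel convention).
affinity_edges <- function(aff) {
  da <- dim(aff)
  d <- da[2:4]
  res <- list()
  grab <- function(axis) {
    nz <- d[1]; ny <- d[2]; nx <- d[3]
    if (axis == 1 && nz < 2) return(NULL)
    if (axis == 2 && ny < 2) return(NULL)
    if (axis == 3 && nx < 2) return(NULL)
    zr <- if (axis == 1) seq_len(nz - 1) else seq_len(nz)
    yr <- if (axis == 2) seq_len(ny - 1) else seq_len(ny)
    xr <- if (axis == 3) seq_len(nx - 1) else seq_len(nx)
    g <- expand.grid(z = zr, y = yr, x = xr)
    a <- vox_lin(g$z, g$y, g$x, d)
    off <- c(0L, 0L, 0L); off[axis] <- 1L
    b <- vox_lin(g$z + off[1], g$y + off[2], g$x + off[3], d)
    w <- aff[cbind(axis, g$z, g$y, g$x)]
    data.frame(a = a, b = b, aff = w)
  }
  out <- do.call(rbind, lapply(1:3, grab))
  rownames(out) <- NULL
  out
}

# Union-find (roots found by walking; unions always point the larger root
# at the smaller, keeping trees shallow for our sizes).
uf_new <- function(n) seq_len(n)

uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

# all roots at once by vectorized pointer jumping
uf_roots <- function(parent) {
  r <- parent
  repeat {
    r2 <- parent[r]
    if (identical(r2, r)) break
    r <- r2
  }
  r
}

# ---- watershed ---------------------------------------------------------

#' Seeded watershed supervoxels from an affinity volume
#'
#' Seeds are the connected components of the subgraph of edges with
#' affinity >= `frag_threshold_hi` (restricted to voxels whose maximal
#' incident affinity reaches the threshold). The flood then processes edges
#' in decreasing affinity order down to `frag_threshold_lo`, growing seed
#' labels along maximum-affinity (bottleneck-optimal) paths; two distinct
#' seeds never merge. Voxels not reached by any seed keep label 0.
#' Fully deterministic: edge ties are broken by the lexicographic
#' (z, y, x) order of the anchor voxel.
#'
#' @param aff affinity array (3, z, y, x), values in `[0, 1]`.
#' @param frag_threshold_hi seed threshold.
#' @param frag_threshold_lo flood floor.
#' @return integer label array (z, y, x); labels are 1..n_seeds in seed
#'   discovery order (lexicographic by seed minimum voxel).
#' @export
watershed_fragments <- function(aff, frag_threshold_hi = 0.9,
                                frag_threshold_lo = 0.2) {
  if (frag_threshold_hi < 0 || frag_threshold_hi > 1 ||
      frag_threshold_lo < 0 || frag_threshold_lo > 1) {
    stop("thresholds must lie in [0, 1]")
  }
  if (frag_threshold_hi <= frag_threshold_lo) {
    stop("frag_threshold_hi must exceed frag_threshold_lo")
  }
  d <- dim(aff)[2:4]
  n <- prod(d)
  ed <- affinity_edges(aff)
  # seeds: components over high-affinity edges
  parent <- uf_new(n)
  hi <- ed[ed$aff >= frag_threshold_hi, , drop = FALSE]
  for (i in seq_len(nrow(hi))) {
    ra <- uf_find(parent, hi$a[i]); rb <- uf_find(parent, hi$b[i])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- uf_roots(parent)
  seeded_vox <- unique(c(hi$a, hi$b))
  labels <- integer(n)
  if (length(seeded_vox) > 0) {
    seed_roots <- unique(roots[seeded_vox])
    # deterministic label order: by lexicographic key of each seed's
    # minimal voxel
    rep_key <- vapply(seed_roots, function(r) {
      min(vox_key(which(roots == r), d))
    }, 0)
    seed_roots <- seed_roots[order(rep_key)]
    for (li in seq_along(seed_roots)) {
      labels[roots == seed_roots[li]] <- li
    }
  }
  # flood: descending affinity >= lo; a labeled side absorbs an unlabeled
  # side; distinct labels never merge
  fl <- ed[ed$aff >= frag_threshold_lo, , drop = FALSE]
  ord <- order(-fl$aff, vox_key(fl$a, d), vox_key(fl$b, d))
  fl <- fl[ord, , drop = FALSE]
  parent2 <- uf_new(n)
  comp_label <- labels  # per-root label, maintained on roots
  for (i in seq_len(nrow(fl))) {
    ra <- uf_find(parent2, fl$a[i]); rb <- uf_find(parent2, fl$b[i])
    if (ra == rb) next
    la <- comp_label[ra]; lb <- comp_label[rb]
    if (la > 0L && lb > 0L && la != lb) next
    keep <- min(ra, rb); drop <- max(ra, rb)
    parent2[drop] <- keep
    comp_label[keep] <- max(la, lb)
  }
  roots2 <- uf_roots(parent2)
  out <- comp_label[roots2]
  array(out, dim = d)
}

# ---- region adjacency graph and agglomeration --------------------------

#' Build a region adjacency graph with agglomeration merge scores
#'
#' Collects every contact edge between touching supervoxels with its
#' boundary affinities, then hierarchically agglomerates clusters in order
#' of decreasing linkage affinity (ties: smaller cluster id pair). When the
#' clusters containing a contact edge's two endpoints first join, the edge
#' receives merge score `1 - (linkage affinity at that step)`.
#'
#' @param supervoxels integer label array (z, y, x); 0 = unassigned.
#' @param aff affinity array (3, z, y, x) of matching shape.
#' @param linkage "mean" (boundary-affinity mean, default) or "max".
#' @return a `region_graph`: `nodes` (data.frame id, z, y, x center of
#'   mass, size) and `edges` (data.frame a, b, merge_score, mean_aff,
#'   max_aff, n_contacts), plus `linkage`.
#' @export
build_rag <- function(supervoxels, aff, linkage = c("mean", "max")) {
  linkage <- match.arg(linkage)
  d <- dim(supervoxels)
  if (!identical(as.integer(dim(aff)[2:4]), as.integer(d))) {
    stop("label and affinity shapes do not match")
  }
  idx <- which(supervoxels > 0L)
  pos <- vox_zyx(idx, d)
  lab <- supervoxels[idx]
  nodes <- data.frame(
    id = sort(unique(lab)),
    z = as.vector(tapply(pos[, 1], lab, mean)),
    y = as.vector(tapply(pos[, 2], lab, mean)),
    x = as.vector(tapply(pos[, 3], lab, mean)),
    size = as.vector(table(lab)))
  ed <- affinity_edges(aff)
  la <- supervoxels[ed$a]; lb <- supervoxels[ed$b]
  keep <- la > 0L & lb > 0L & la != lb
  cont <- data.frame(a = pmin(la[keep], lb[keep]),
                     b = pmax(la[keep], lb[keep]),
                     aff = ed$aff[keep])
  if (nrow(cont) == 0) {
    return(structure(list(nodes = nodes,
                          edges = data.frame(a = integer(), b = integer(),
                                             merge_score = numeric(),
                                             mean_aff = numeric(),
                                             max_aff = numeric(),
                                             n_contacts = integer()),
                          linkage = linkage),
                     class = "region_graph"))
  }
  key <- paste(cont$a, cont$b)
  agg <- data.frame(
    a = cont$a[!duplicated(key)],
    b = cont$b[!duplicated(key)],
    sum_aff = as.vector(tapply(cont$aff, key, sum)[unique(key)]),
    max_aff = as.vector(tapply(cont$aff, key, max)[unique(key)]),
    n_contacts = as.vector(tapply(cont$aff, key, length)[unique(key)]))
  agg$mean_aff <- agg$sum_aff / agg$n_contacts
  agg <- agg[order(agg$a, agg$b), ]
  rownames(agg) <- NULL
  scores <- agglomerate_scores(agg, linkage)
  edges <- data.frame(a = agg$a, b = agg$b, merge_score = scores,
                      mean_aff = agg$mean_aff, max_aff = agg$max_aff,
                      n_contacts = agg$n_contacts)
  structure(list(nodes = nodes, edges = edges, linkage = linkage),
            class = "region_graph")
}

# Hierarchical agglomeration over cluster pairs; returns per input edge the
# merge score (1 - linkage affinity when its endpoints first share a
# cluster).
agglomerate_scores <- function(agg, linkage) {
  ids <- sort(unique(c(agg$a, agg$b)))
  remap <- stats::setNames(seq_along(ids), ids)
  n <- length(ids)
  ea <- remap[as.character(agg$a)]; eb <- remap[as.character(agg$b)]
  # cluster-pair state
  pk <- function(i, j) paste(min(i, j), max(i, j))
  sum_w <- new.env(parent = emptyenv())
  max_w <- new.env(parent = emptyenv())
  cnt_w <- new.env(parent = emptyenv())
  members <- new.env(parent = emptyenv())  # original edge rows per pair
  for (r in seq_len(nrow(agg))) {
    k <- pk(ea[r], eb[r])
    assign(k, agg$sum_aff[r], sum_w)
    assign(k, agg$max_aff[r], max_w)
    assign(k, agg$n_contacts[r], cnt_w)
    assign(k, r, members)
  }
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  link_aff <- function(k) {
    if (linkage == "max") get(k, max_w) else get(k, sum_w) / get(k, cnt_w)
  }
  scores <- rep(NA_real_, nrow(agg))
  active <- function() ls(members)
  repeat {
    keys <- active()
    if (length(keys) == 0) break
    affs <- vapply(keys, link_aff, 0)
    best <- keys[order(-affs, keys)][1]
    w <- max(affs)
    ij <- as.integer(strsplit(best, " ")[[1]])
    i <- ij[1]; j <- ij[2]
    # record scores for the original edges between these clusters
    scores[get(best, members)] <- 1 - w
    # merge j into i: rewire all pairs involving j
    rm(list = best, envir = members)
    rm(list = best, envir = sum_w); rm(list = best, envir = max_w)
    rm(list = best, envir = cnt_w)
    for (k in active()) {
      uv <- as.integer(strsplit(k, " ")[[1]])
      if (!(j %in% uv)) next
      other <- setdiff(uv, j)
      k2 <- pk(i, other)
      if (exists(k2, members, inherits = FALSE)) {
        assign(k2, get(k2, sum_w) + get(k, sum_w), sum_w)
        assign(k2, max(get(k2, max_w), get(k, max_w)), max_w)
        assign(k2, get(k2, cnt_w) + get(k, cnt_w), cnt_w)
        assign(k2, c(get(k2, members), get(k, members)), members)
      } else {
        assign(k2, get(k, sum_w), sum_w)
        assign(k2, get(k, max_w), max_w)
        assign(k2, get(k, cnt_w), cnt_w)
        assign(k2, get(k, members), members)
      }
      rm(list = k, envir = members)
      rm(list = k, envir = sum_w); rm(list = k, envir = max_w)
      rm(list = k, envir = cnt_w)
    }
    # relabel cluster j as i in future keys: handled by rewiring above;
    # parent kept for completeness
    parent[j] <- i
  }
  scores
}

#' Final segmentation at a merge-score threshold
#'
#' Keeps region-graph edges with merge score <= `t`, computes connected
#' components, and relabels the supervoxel volume; each component's label
#' is its minimum member supervoxel id.
#'
#' @param rag a `region_graph` from [build_rag()].
#' @param supervoxels the matching supervoxel volume.
#' @param t merge-score threshold in `[0, 1]`.
#' @return relabeled integer volume.
#' @export
segment_at_threshold <- function(rag, supervoxels, t) {
  if (t < 0 || t > 1) stop("threshold must lie in [0, 1]")
  ids <- rag$nodes$id
  remap <- stats::setNames(seq_along(ids), ids)
  parent <- seq_along(ids)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  keep <- rag$edges[rag$edges$merge_score <= t, , drop = FALSE]
  for (r in seq_len(nrow(keep))) {
    ra <- find(remap[as.character(keep$a[r])])
    rb <- find(remap[as.character(keep$b[r])])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  comp <- vapply(seq_along(ids), function(i) find(i), 0L)
  newlab <- vapply(seq_along(ids), function(i) {
    min(ids[comp == comp[i]])
  }, 0L)
  lut <- integer(max(ids) + 1L)
  lut[ids + 1L] <- newlab
  out <- supervoxels
  pos <- supervoxels > 0L
  out[pos] <- lut[supervoxels[pos] + 1L]
  out
}

# ---- graphene ids (64-bit) ---------------------------------------------

#' Chunked-graph layout
#'
#' Defines the chunking scheme and the 64-bit label encoding: from the most
#' significant bits down, the layer id, then the x, y, z chunk coordinates,
#' then the in-chunk segment id.
#'
#' @param chunk_size voxels (cz, cy, cx).
#' @param layer_bits,bits_per_coord,segment_bits bit widths; their total
#'   (layer + 3 x coord + segment) must not exceed 64.
#' @return a `chunk_layout`.
#' @export
chunk_layout <- function(chunk_size = c(64L, 64L, 64L), layer_bits = 8L,
                         bits_per_coord = 10L, segment_bits = 26L) {
  if (layer_bits + 3 * bits_per_coord + segment_bits > 64) {
    stop("bit budget exceeds 64")
  }
  structure(list(chunk_size = as.integer(chunk_size),
                 layer_bits = as.integer(layer_bits),
                 bits_per_coord = as.integer(bits_per_coord),
                 segment_bits = as.integer(segment_bits)),
            class = "chunk_layout")
}

# -- exact unsigned 64-bit arithmetic on 4 x 16-bit limbs (limb 1 = least
#    significant); ids are exposed as decimal strings because R doubles
#    cannot hold 64-bit integers exactly.

u64_zero <- function() c(0L, 0L, 0L, 0L)

u64_norm <- function(l) {
  carry <- 0
  for (i in 1:4) {
    v <- l[i] + carry
    l[i] <- v %% 65536
    carry <- v %/% 65536
  }
  if (carry != 0) stop("u64 overflow")
  as.integer(l)
}

# add field << shift into limbs (field < 2^53, non-overlapping layout)
u64_add_shifted <- function(l, field, shift) {
  field <- as.numeric(field)
  while (field > 0) {
    limb <- shift %/% 16 + 1
    off <- shift %% 16
    if (limb > 4) stop("u64 overflow")
    chunkbits <- 16 - off
    part <- field %% 2^chunkbits
    l[limb] <- l[limb] + part * 2^off
    field <- field %/% 2^chunkbits
    shift <- shift + chunkbits
  }
  u64_norm(l)
}

u64_extract <- function(l, shift, nbits) {
  # value of bits [shift, shift + nbits) as a double (nbits <= 53)
  out <- 0
  for (b in seq_len(nbits)) {
    bit <- shift + b - 1
    limb <- bit %/% 16 + 1
    off <- bit %% 16
    bitval <- (l[limb] %/% 2^off) %% 2
    out <- out + bitval * 2^(b - 1)
  }
  out
}

u64_to_decimal <- function(l) {
  digits <- character(0)
  l <- as.numeric(l)
  repeat {
    if (all(l == 0)) break
    rem <- 0
    for (i in 4:1) {
      cur <- rem * 65536 + l[i]
      l[i] <- cur %/% 10
      rem <- cur %% 10
    }
    digits <- c(as.character(rem), digits)
  }
  if (length(digits) == 0) "0" else paste(digits, collapse = "")
}

u64_from_decimal <- function(s) {
  l <- c(0, 0, 0, 0)
  for (ch in strsplit(s, "")[[1]]) {
    dgt <- as.numeric(ch)
    if (is.na(dgt)) stop("invalid decimal id: ", s)
    carry <- dgt
    for (i in 1:4) {
      cur <- l[i] * 10 + carry
      l[i] <- cur %% 65536
      carry <- cur %/% 65536
    }
    if (carry != 0) stop("u64 overflow parsing ", s)
  }
  as.integer(l)
}

#' Encode / decode graphene ids
#'
#' A graphene id packs, from the most significant bits, the chunked-graph
#' layer, the x, y, z chunk coordinates, and the in-chunk segment id. Ids
#' are returned as decimal strings (64-bit values exceed R's exact double
#' range).
#'
#' @param layer layer id (>= 1).
#' @param chunk_coord integer (cx, cy, cz), 0-based chunk indices.
#' @param segment in-chunk segment id (>= 0).
#' @param layout a [chunk_layout()].
#' @return `encode_graphene_id`: decimal string; `decode_graphene_id`:
#'   list(layer, chunk_coord, segment).
#' @export
encode_graphene_id <- function(layer, chunk_coord, segment, layout) {
  b <- layout$bits_per_coord; s <- layout$segment_bits
  if (layer < 0 || layer >= 2^layout$layer_bits) stop("layer overflows")
  if (any(chunk_coord < 0) || any(chunk_coord >= 2^b)) {
    stop("chunk coordinate overflows")
  }
  if (segment < 0 || segment >= 2^s) stop("segment id overflows")
  l <- u64_zero()
  l <- u64_add_shifted(l, segment, 0)
  l <- u64_add_shifted(l, chunk_coord[3], s)
  l <- u64_add_shifted(l, chunk_coord[2], s + b)
  l <- u64_add_shifted(l, chunk_coord[1], s + 2 * b)
  l <- u64_add_shifted(l, layer, s + 3 * b)
  u64_to_decimal(l)
}

#' @rdname encode_graphene_id
#' @param id decimal-string graphene id.
#' @export
decode_graphene_id <- function(id, layout) {
  b <- layout$bits_per_coord; s <- layout$segment_bits
  l <- u64_from_decimal(id)
  list(layer = u64_extract(l, s + 3 * b, layout$layer_bits),
       chunk_coord = c(u64_extract(l, s + 2 * b, b),
                       u64_extract(l, s + b, b),
                       u64_extract(l, s, b)),
       segment = u64_extract(l, 0, s))
}

# numeric comparison of decimal-string u64 ids
u64_less <- function(a, b) {
  if (nchar(a) != nchar(b)) return(nchar(a) < nchar(b))
  a < b
}

u64_min <- function(ids) {
  m <- ids[1]
  for (i in seq_along(ids)[-1]) if (u64_less(ids[i], m)) m <- ids[i]
  m
}

# ---- chunking ----------------------------------------------------------

#' Split supervoxels into chunked-graph fragments
#'
#' Restricted to each chunk, the connected components (6-connectivity) of
#' every original supervoxel become fresh fragments with per-chunk segment
#' ids, encoded as layer-1 graphene ids. Face-adjacent voxel pairs across a
#' chunk boundary that share an original label yield one deduplicated
#' cross-chunk edge (at maximal affinity) reconnecting the split fragments.
#'
#' @param supervoxels integer label volume (z, y, x), 0 = background.
#' @param layout a [chunk_layout()].
#' @return list: `fragment_volume` (integer volume of fragment indices, 0 =
#'   background), `fragments` (data.frame: index, id (graphene string),
#'   orig_label, chunk x/y/z, segment, size), `id_map` (list per chunk:
#'   original label -> graphene ids), `cross_edges` (data.frame id_a, id_b,
#'   affinity = 1).
#' @export
chunk_supervoxels <- function(supervoxels, layout) {
  d <- dim(supervoxels)
  cs <- layout$chunk_size
  ncz <- ceiling(d[1] / cs[1]); ncy <- ceiling(d[2] / cs[2])
  ncx <- ceiling(d[3] / cs[3])
  if (any(c(ncx, ncy, ncz) > 2^layout$bits_per_coord)) {
    stop("chunk grid exceeds the coordinate bit budget")
  }
  frag_vol <- array(0L, d)
  fragments <- list()
  id_map <- list()
  next_index <- 0L
  for (cz in seq_len(ncz)) for (cy in seq_len(ncy)) for (cx in seq_len(ncx)) {
    zr <- ((cz - 1) * cs[1] + 1):min(cz * cs[1], d[1])
    yr <- ((cy - 1) * cs[2] + 1):min(cy * cs[2], d[2])
    xr <- ((cx - 1) * cs[3] + 1):min(cx * cs[3], d[3])
    sub <- supervoxels[zr, yr, xr, drop = FALSE]
    dim(sub) <- c(length(zr), length(yr), length(xr))
    comp <- label_components(sub)
    ncomp <- max(comp)
    if (ncomp == 0) next
    if (ncomp > 2^layout$segment_bits) {
      stop(sprintf("chunk (%d,%d,%d) holds %d fragments > 2^%d capacity",
                   cx - 1, cy - 1, cz - 1, ncomp, layout$segment_bits))
    }
    ckey <- sprintf("%d_%d_%d", cx - 1, cy - 1, cz - 1)
    id_map[[ckey]] <- list()
    for (ci in seq_len(ncomp)) {
      vox <- which(comp == ci)
      orig <- sub[vox[1]]
      gid <- encode_graphene_id(1, c(cx - 1, cy - 1, cz - 1), ci - 1, layout)
      next_index <- next_index + 1L
      fragments[[next_index]] <- data.frame(
        index = next_index, id = gid, orig_label = orig,
        chunk_x = cx - 1, chunk_y = cy - 1, chunk_z = cz - 1,
        segment = ci - 1, size = length(vox),
        stringsAsFactors = FALSE)
      id_map[[ckey]][[as.character(orig)]] <-
        c(id_map[[ckey]][[as.character(orig)]], gid)
      tmp <- array(0L, dim(sub)); tmp[vox] <- next_index
      frag_vol[zr, yr, xr] <- frag_vol[zr, yr, xr] + tmp
    }
  }
  fragments <- do.call(rbind, fragments)
  # cross-chunk edges: face pairs across chunk boundaries, equal orig label
  cross <- chunk_boundary_pairs(supervoxels, frag_vol, cs, same_label = TRUE)
  cross_edges <- if (nrow(cross) == 0) {
    data.frame(id_a = character(), id_b = character(), affinity = numeric(),
               stringsAsFactors = FALSE)
  } else {
    data.frame(id_a = fragments$id[cross$fa], id_b = fragments$id[cross$fb],
               affinity = 1, stringsAsFactors = FALSE)
  }
  list(fragment_volume = frag_vol, fragments = fragments, id_map = id_map,
       cross_edges = cross_edges, layout = layout)
}

# 6-connected components of equal positive labels; component ids assigned
# in lexicographic (z, y, x) order of each component's first voxel.
# Background (0) stays 0. Exact connected components by iterated min-index
# propagation (vectorized; converges within the component diameter).
label_components <- function(vol) {
  d <- dim(vol)
  n <- prod(d)
  comp <- array(seq_len(n), d)
  comp[vol == 0L] <- 0L
  shrink <- function(m, axis, side) {
    # neighbor view along +/- axis with same-label mask applied
    idx_keep <- lapply(d, seq_len)
    idx_nb <- idx_keep
    if (side > 0) {
      idx_keep[[axis]] <- seq_len(d[axis] - 1)
      idx_nb[[axis]] <- 2:d[axis]
    } else {
      idx_keep[[axis]] <- 2:d[axis]
      idx_nb[[axis]] <- seq_len(d[axis] - 1)
    }
    list(keep = idx_keep, nb = idx_nb)
  }
  repeat {
    before <- comp
    for (axis in 1:3) {
      if (d[axis] < 2) next
      for (side in c(1, -1)) {
        ix <- shrink(comp, axis, side)
        a <- do.call(`[`, c(list(vol), ix$keep, list(drop = FALSE)))
        b <- do.call(`[`, c(list(vol), ix$nb, list(drop = FALSE)))
        ca <- do.call(`[`, c(list(comp), ix$keep, list(drop = FALSE)))
        cb <- do.call(`[`, c(list(comp), ix$nb, list(drop = FALSE)))
        upd <- a > 0L & a == b & cb < ca & cb > 0L
        ca[upd] <- cb[upd]
        comp <- do.call(`[<-`, c(list(comp), ix$keep, list(ca)))
      }
    }
    if (identical(comp, before)) break
  }
  # renumber deterministically by each component's lexicographically first
  # voxel
  fg <- vol > 0L
  if (!any(fg)) return(array(0L, d))
  keys <- vox_key(which(fg), d)
  min_key <- tapply(keys, comp[fg], min)
  ord <- names(sort(min_key))
  lut <- stats::setNames(seq_along(ord), ord)
  out <- array(0L, d)
  out[fg] <- as.integer(lut[as.character(comp[fg])])
  out
}

# Face-adjacent voxel pairs that straddle a chunk boundary. Returns
# fragment index pairs (fa, fb); with same_label=TRUE only pairs sharing
# the original label, deduplicated.
chunk_boundary_pairs <- function(supervoxels, frag_vol, cs,
                                 same_label = TRUE) {
  d <- dim(supervoxels)
  res <- list()
  for (axis in 1:3) {
    bnd <- seq_len(max(0L, (d[axis] - 1L) %/% cs[axis])) * cs[axis]
    if (length(bnd) == 0) next
    for (pos in bnd) {
      if (axis == 1) {
        la <- supervoxels[pos, , , drop = FALSE]
        lb <- supervoxels[pos + 1, , , drop = FALSE]
        fa <- frag_vol[pos, , , drop = FALSE]
        fb <- frag_vol[pos + 1, , , drop = FALSE]
      } else if (axis == 2) {
        la <- supervoxels[, pos, , drop = FALSE]
        lb <- supervoxels[, pos + 1, , drop = FALSE]
        fa <- frag_vol[, pos, , drop = FALSE]
        fb <- frag_vol[, pos + 1, , drop = FALSE]
      } else {
        la <- supervoxels[, , pos, drop = FALSE]
        lb <- supervoxels[, , pos + 1, drop = FALSE]
        fa <- frag_vol[, , pos, drop = FALSE]
        fb <- frag_vol[, , pos + 1, drop = FALSE]
      }
      keep <- la > 0L & lb > 0L
      if (same_label) keep <- keep & la == lb
      if (!any(keep)) next
      res[[length(res) + 1]] <- data.frame(fa = fa[keep], fb = fb[keep])
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) return(data.frame(fa = integer(), fb = integer()))
  out <- unique(data.frame(fa = pmin(out$fa, out$fb),
                           fb = pmax(out$fa, out$fb)))
  rownames(out) <- NULL
  out
}

# ---- edge classification and initial agglomeration ---------------------

#' Classify chunked-graph edges
#'
#' Translates region-graph edges to fragment (graphene id) pairs using the
#' fragment contact relation, and classifies every edge: `in_chunk` (both
#' endpoints in the same chunk), `between_chunk` (different chunks), and
#' `cross_chunk` (fragments of one split supervoxel, from
#' [chunk_supervoxels()]). Edge affinity is `1 - merge_score`; cross-chunk
#' edges carry the fixed maximal affinity 1.
#'
#' @param chunked result of [chunk_supervoxels()].
#' @param rag the `region_graph` over original supervoxel labels.
#' @param supervoxels the original supervoxel volume.
#' @return a `chunked_edge_set`: data.frames `in_chunk`, `between_chunk`,
#'   `cross_chunk` with columns id_a, id_b, affinity.
#' @export
classify_edges <- function(chunked, rag, supervoxels) {
  fr <- chunked$fragments
  # fragment-level contacts between different original labels
  pairs <- chunk_boundary_pairs(supervoxels, chunked$fragment_volume,
                                chunked$layout$chunk_size,
                                same_label = FALSE)
  # also contacts wholly inside chunks
  inside <- fragment_contacts_within(chunked$fragment_volume)
  allp <- unique(rbind(pairs, inside))
  la <- fr$orig_label[allp$fa]; lb <- fr$orig_label[allp$fb]
  diff_lab <- la != lb
  allp <- allp[diff_lab, , drop = FALSE]
  la <- la[diff_lab]; lb <- lb[diff_lab]
  if (nrow(allp) > 0) {
    ek <- paste(pmin(la, lb), pmax(la, lb))
    sc <- stats::setNames(rag$edges$merge_score,
                          paste(rag$edges$a, rag$edges$b))
    aff <- 1 - unname(sc[ek])
    if (any(is.na(aff))) stop("fragment contact without a mapped RAG edge")
  } else {
    aff <- numeric(0)
  }
  same_chunk <- fr$chunk_x[allp$fa] == fr$chunk_x[allp$fb] &
    fr$chunk_y[allp$fa] == fr$chunk_y[allp$fb] &
    fr$chunk_z[allp$fa] == fr$chunk_z[allp$fb]
  mk <- function(sel) {
    data.frame(id_a = fr$id[allp$fa[sel]], id_b = fr$id[allp$fb[sel]],
               affinity = aff[sel], stringsAsFactors = FALSE)
  }
  structure(list(in_chunk = mk(same_chunk),
                 between_chunk = mk(!same_chunk),
                 cross_chunk = chunked$cross_edges),
            class = "chunked_edge_set")
}

# deduplicated fragment contact pairs (6-conn) anywhere in the volume
fragment_contacts_within <- function(frag_vol) {
  d <- dim(frag_vol)
  res <- list()
  grab <- function(axis) {
    nz <- d[1]; ny <- d[2]; nx <- d[3]
    zr <- if (axis == 1) seq_len(max(nz - 1, 0)) else seq_len(nz)
    yr <- if (axis == 2) seq_len(max(ny - 1, 0)) else seq_len(ny)
    xr <- if (axis == 3) seq_len(max(nx - 1, 0)) else seq_len(nx)
    if (!length(zr) || !length(yr) || !length(xr)) return(NULL)
    g <- expand.grid(z = zr, y = yr, x = xr)
    off <- c(0L, 0L, 0L); off[axis] <- 1L
    a <- vox_lin(g$z, g$y, g$x, d)
    b <- vox_lin(g$z + off[1], g$y + off[2], g$x + off[3], d)
    fa <- frag_vol[a]; fb <- frag_vol[b]
    keep <- fa > 0L & fb > 0L & fa != fb
    data.frame(fa = fa[keep], fb = fb[keep])
  }
  out <- do.call(rbind, lapply(1:3, grab))
  if (is.null(out)) return(data.frame(fa = integer(), fb = integer()))
  unique(data.frame(fa = pmin(out$fa, out$fb), fb = pmax(out$fa, out$fb)))
}

#' Initial agglomeration of the chunked graph
#'
#' Builds a graph over graphene ids from the classified edges, discards
#' in-chunk and between-chunk edges whose merge score (`1 - affinity`)
#' exceeds `threshold`, optionally splits connected components at chunk
#' boundaries (discarding between-chunk and cross-chunk edges so the
#' initial proofreading state is fragmented at regular intervals), and
#' labels the connected components deterministically by their minimum
#' member id.
#'
#' @param edge_set a `chunked_edge_set` from [classify_edges()].
#' @param fragments the fragment table from [chunk_supervoxels()].
#' @param threshold merge-score threshold in `[0, 1]`.
#' @param split_at_chunk_boundaries logical.
#' @return named character vector: graphene id -> component id (the
#'   minimum member graphene id).
#' @export
initial_agglomeration <- function(edge_set, fragments, threshold,
                                  split_at_chunk_boundaries = FALSE) {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  ids <- fragments$id
  n <- length(ids)
  remap <- stats::setNames(seq_len(n), ids)
  keep_edges <- list()
  filt <- function(df) df[(1 - df$affinity) <= threshold, , drop = FALSE]
  keep_edges$inc <- filt(edge_set$in_chunk)
  if (!split_at_chunk_boundaries) {
    keep_edges$btw <- filt(edge_set$between_chunk)
    keep_edges$crs <- edge_set$cross_chunk
  }
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (df in keep_edges) {
    for (r in seq_len(nrow(df))) {
      ra <- find(remap[[df$id_a[r]]]); rb <- find(remap[[df$id_b[r]]])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  comp <- vapply(seq_len(n), function(i) find(i), 0L)
  out <- character(n)
  for (cc in unique(comp)) {
    sel <- comp == cc
    out[sel] <- u64_min(ids[sel])
  }
  stats::setNames(out, ids)
}

#' Write a chunked edge set to disk
#'
#' One sorted CSV per (chunk, class) plus a JSON schema sidecar, mirroring
#' per-chunk upload granularity.
#'
#' @param edge_set a `chunked_edge_set`.
#' @param fragments fragment table (for chunk lookup of id_a).
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
export_edges <- function(edge_set, fragments, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  chunk_of <- stats::setNames(
    sprintf("%d_%d_%d", fragments$chunk_x, fragments$chunk_y,
            fragments$chunk_z), fragments$id)
  for (cls in c("in_chunk", "between_chunk", "cross_chunk")) {
    df <- edge_set[[cls]]
    if (nrow(df) == 0) next
    ck <- chunk_of[df$id_a]
    for (c1 in unique(ck)) {
      sub <- df[ck == c1, , drop = FALSE]
      sub <- sub[order(sub$id_a, sub$id_b), ]
      utils::write.csv(sub,
                       file.path(dir, sprintf("edges_%s_%s.csv", cls, c1)),
                       row.names = FALSE)
    }
  }
  jsonlite::write_json(
    list(columns = c("id_a", "id_b", "affinity"),
         id_type = "uint64 decimal string", affinity_type = "float32",
         classes = c("in_chunk", "between_chunk", "cross_chunk")),
    file.path(dir, "schema.json"), auto_unbox = TRUE)
  invisible(dir)
}
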