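# Independent brute-force oracles shared by the segmentation-graph and
# acceptance suites.

# --- independent oracles (deliberately naive implementations) -----------

# brute-force seeded watershed: repeated scans instead of sorted union-find
oracle_watershed <- function(aff, hi, lo) {
  d <- dim(aff)[2:4]
  ed <- mrvem:::affinity_edges(aff)
  n <- prod(d)
  # seeds: igraph components over high edges
  keep <- ed$aff >= hi
  lab <- igraph_components(n, ed$a[keep], ed$b[keep])
  seeded <- rep(FALSE, n)
  seeded[c(ed$a[keep], ed$b[keep])] <- TRUE
  out <- integer(n)
  comp_ids <- unique(lab[seeded])
  # label seeds in lexicographic order of their minimal voxel
  keyfun <- function(c1) min(mrvem:::vox_key(which(lab == c1 & seeded), d))
  comp_ids <- comp_ids[order(vapply(comp_ids, keyfun, 0))]
  for (i in seq_along(comp_ids)) out[lab == comp_ids[i] & seeded] <- i
  # flood: repeatedly take the globally best labeled-unlabeled edge
  fl <- ed[ed$aff >= lo, , drop = FALSE]
  fl <- fl[order(-fl$aff, mrvem:::vox_key(fl$a, d),
                 mrvem:::vox_key(fl$b, d)), , drop = FALSE]
  repeat {
    grew <- FALSE
    for (i in seq_len(nrow(fl))) {
      la <- out[fl$a[i]]; lb <- out[fl$b[i]]
      if (la > 0L && lb == 0L) { out[fl$b[i]] <- la; grew <- TRUE; break }
      if (lb > 0L && la == 0L) { out[fl$a[i]] <- lb; grew <- TRUE; break }
    }
    if (!grew) break
  }
  array(out, d)
}

# brute-force agglomeration scores by explicit cluster bookkeeping over
# data.frames (the implementation uses environments keyed by pair)
oracle_scores <- function(edges, linkage) {
  cl <- stats::setNames(as.list(unique(c(edges$a, edges$b))),
                        unique(c(edges$a, edges$b)))
  # cluster membership: label -> cluster name
  memb <- stats::setNames(as.character(unique(c(edges$a, edges$b))),
                          unique(c(edges$a, edges$b)))
  sc <- rep(NA_real_, nrow(edges))
  while (any(is.na(sc))) {
    # linkage affinity per open cluster pair
    ca <- memb[as.character(edges$a)]
    cb <- memb[as.character(edges$b)]
    open <- ca != cb
    if (!any(open)) break
    key <- paste(pmin(ca, cb), pmax(ca, cb))
    kk <- key[open]
    linkv <- if (linkage == "max") {
      tapply(edges$max_aff[open], kk, max)
    } else {
      tapply(edges$sum_aff[open], kk, sum) /
        tapply(edges$n_contacts[open], kk, sum)
    }
    best <- names(linkv)[order(-linkv, names(linkv))][1]
    hit <- open & key == best
    sc[hit] <- 1 - linkv[[best]]
    # merge the two clusters of `best`
    parts <- strsplit(best, " ")[[1]]
    memb[memb == parts[2]] <- parts[1]
  }
  sc
}

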