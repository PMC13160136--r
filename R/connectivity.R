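# Synapse-to-circuit extraction: label assignment, confidence filtering,
# autapse removal, and aggregation into a filtered connectivity table.

#' Assign segmentation labels to synapse sites
#'
#' Annotates each predicted pre/post voxel pair with the label under it.
#' Rows where either side is out of bounds or hits background (label 0)
#' are dropped; their count is reported in attributes.
#'
#' @param synapses data.frame with columns pre_z, pre_y, pre_x, post_z,
#'   post_y, post_x, score (voxel coordinates, 1-based).
#' @param label_volume integer array (z, y, x).
#' @return the labeled table (added columns pre_label, post_label) with
#'   attributes `n_dropped_oob` and `n_dropped_background`.
#' @export
assign_synapse_labels <- function(synapses, label_volume) {
  d <- dim(label_volume)
  inb <- function(z, y, x) {
    z >= 1 & z <= d[1] & y >= 1 & y <= d[2] & x >= 1 & x <= d[3]
  }
  ok_pre <- inb(synapses$pre_z, synapses$pre_y, synapses$pre_x)
  ok_post <- inb(synapses$post_z, synapses$post_y, synapses$post_x)
  oob <- !(ok_pre & ok_post)
  kept <- synapses[!oob, , drop = FALSE]
  pre_l <- label_volume[cbind(kept$pre_z, kept$pre_y, kept$pre_x)]
  post_l <- label_volume[cbind(kept$post_z, kept$post_y, kept$post_x)]
  bg <- pre_l == 0L | post_l == 0L
  out <- kept[!bg, , drop = FALSE]
  out$pre_label <- pre_l[!bg]
  out$post_label <- post_l[!bg]
  rownames(out) <- NULL
  attr(out, "n_dropped_oob") <- sum(oob)
  attr(out, "n_dropped_background") <- sum(bg)
  out
}

#' Filter synapses by prediction confidence
#'
#' @param labeled labeled synapse table.
#' @param min_score rows with score below this are removed.
#' @return filtered table.
#' @export
filter_confidence <- function(labeled, min_score) {
  if (min_score < 0 || min_score > 1) stop("min_score must lie in [0, 1]")
  out <- labeled[labeled$score >= min_score, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove autapses
#'
#' Synapses connecting a label to itself are treated as prediction
#' artifacts and removed.
#'
#' @param labeled labeled synapse table.
#' @return table without rows where pre_label == post_label.
#' @export
remove_autapses <- function(labeled) {
  out <- labeled[labeled$pre_label != labeled$post_label, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate synapses into a filtered connectivity table
#'
#' Counts synapses per directed (pre, post) label pair and discards weak
#' connections. The default `min_synapses = 4` keeps connections with at
#' least four synapses, i.e. discards any connection with three or fewer.
#'
#' @param labeled labeled synapse table (after filtering).
#' @param min_synapses smallest count retained (>= 1).
#' @param id_map optional data.frame (segment_id, neuron_id): labels are
#'   mapped to proofread neuron identities before counting.
#' @return data.frame pre, post, n_synapses, sorted by decreasing count.
#' @export
aggregate_connections <- function(labeled, min_synapses = 4L,
                                  id_map = NULL) {
  if (min_synapses < 1) stop("min_synapses must be >= 1")
  pre <- labeled$pre_label
  post <- labeled$post_label
  if (!is.null(id_map)) {
    m <- stats::setNames(id_map$neuron_id, id_map$segment_id)
    pre <- unname(m[as.character(pre)])
    post <- unname(m[as.character(post)])
  }
  if (length(pre) == 0) {
    return(data.frame(pre = integer(), post = integer(),
                      n_synapses = integer()))
  }
  key <- paste(pre, post, sep = "->")
  tab <- table(key)
  parts <- strsplit(names(tab), "->", fixed = TRUE)
  out <- data.frame(pre = vapply(parts, `[`, "", 1),
                    post = vapply(parts, `[`, "", 2),
                    n_synapses = as.integer(tab))
  if (is.numeric(labeled$pre_label) && is.null(id_map)) {
    out$pre <- as.integer(out$pre)
    out$post <- as.integer(out$post)
  }
  out <- out[out$n_synapses >= min_synapses, , drop = FALSE]
  out <- out[order(-out$n_synapses, out$pre, out$post), ]
  rownames(out) <- NULL
  out
}

#' Read / write synapse tables as CSV
#'
#' @param path CSV path with columns pre_z, pre_y, pre_x, post_z, post_y,
#'   post_x, score.
#' @return data.frame.
#' @export
read_synapses <- function(path) {
  df <- utils::read.csv(path)
  needed <- c("pre_z", "pre_y", "pre_x", "post_z", "post_y", "post_x",
              "score")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop("synapse table misses columns: ", paste(missing, collapse = ", "))
  }
  df[needed]
}
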