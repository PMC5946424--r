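# Independent brute-force oracle for branch assignment: enumerate every
# node's descendant leaf set with phangorn, find carrier-pure nodes by
# direct set algebra, and take the maximal ones by full-leaf-set
# containment. Shares no code with patriline::assign_branch.
oracle_assign_branch <- function(carriers, tree, outgroup = NULL,
                                 missing = character()) {
  ntip <- length(tree$tip.label)
  ids <- seq_len(ntip + tree$Nnode)
  sets <- lapply(phangorn::Descendants(tree, ids, type = "tips"),
                 function(i) sort(tree$tip.label[i]))
  eligible <- setdiff(tree$tip.label, outgroup)
  informative <- setdiff(eligible, missing)
  car <- intersect(carriers, informative)
  if (length(car) == 0)
    return(list(status = "uninformative", node = NA_character_,
                top_nodes = character(0)))
  pure <- which(vapply(sets, function(s) {
    inf <- intersect(s, informative)
    length(inf) > 0 && all(inf %in% car) && any(car %in% s)
  }, logical(1)))
  maximal <- pure[vapply(pure, function(p) {
    !any(vapply(pure, function(q)
      length(sets[[q]]) > length(sets[[p]]) &&
        all(sets[[p]] %in% sets[[q]]), logical(1)))
  }, logical(1))]
  labels <- sort(vapply(maximal, function(i)
    paste(sort(intersect(sets[[i]], eligible)), collapse = ","),
    character(1)))
  if (length(labels) == 1L)
    list(status = "diagnostic", node = labels, top_nodes = labels)
  else
    list(status = "incompatible", node = NA_character_,
         top_nodes = labels)
}

# Positionwise threshold oracle for the callability mask (no smoothing, no
# run merging): recomputes pass/fail per position directly.
oracle_mask_positions <- function(track, depth_min, depth_max,
                                  mq0_ratio_max) {
  ratio <- ifelse(track$raw_depth == 0, 0, track$mq0 / track$raw_depth)
  track$filtered_depth >= depth_min & track$filtered_depth <= depth_max &
    ratio <= mq0_ratio_max
}
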