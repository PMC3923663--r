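TIER_NAMES <- c("ligand", "intermediate", "target")

#' A two-link cross-inhibition topology
#'
#' One inhibitory link per direction between the two three-tier pathways
#' (BMP -> B_I -> B_T, FGF -> F_I -> F_T). The F-to-B link is sourced on the
#' FGF side at tier `fb_source_tier` and lands on the BMP side at tier
#' `fb_target_tier`; the B-to-F link mirrors this. Tiers are 0 (ligand),
#' 1 (intermediate), 2 (target).
#'
#' @param fb_source_tier,fb_target_tier,bf_source_tier,bf_target_tier Integer
#'   tier indices in `0:2`.
#' @return An object of class `"ms_topology"` with a `class_label` field set
#'   by [classify_topology()].
#' @export
topology <- function(fb_source_tier, fb_target_tier,
                     bf_source_tier, bf_target_tier) {
  tiers <- c(fb_source_tier, fb_target_tier, bf_source_tier, bf_target_tier)
  if (!all(tiers %in% 0:2)) stop("tier indices must lie in 0:2")
  top <- structure(list(fb_source_tier = as.integer(fb_source_tier),
                        fb_target_tier = as.integer(fb_target_tier),
                        bf_source_tier = as.integer(bf_source_tier),
                        bf_target_tier = as.integer(bf_target_tier),
                        class_label = NA_character_),
                   class = "ms_topology")
  top$class_label <- classify_topology(top)
  top
}

#' @export
print.ms_topology <- function(x, ...) {
  cat(sprintf("topology [%s]: F-side %s -| B-side %s; B-side %s -| F-side %s\n",
              x$class_label,
              TIER_NAMES[x$fb_source_tier + 1], TIER_NAMES[x$fb_target_tier + 1],
              TIER_NAMES[x$bf_source_tier + 1], TIER_NAMES[x$bf_target_tier + 1]))
  invisible(x)
}

#' Classify a cross-inhibition topology
#'
#' A topology is CIPF when its two inhibitory links close a cycle: the B-to-F
#' link is sourced at or downstream of where the F-to-B link lands
#' (`bf_source_tier >= fb_target_tier`) and vice versa
#' (`fb_source_tier >= bf_target_tier`). Without a cycle it is CFF when the
#' B-to-F link still modulates the inhibitor feeding the F-to-B link
#' (`bf_target_tier <= fb_source_tier`), i.e. the BMP pathway coherently
#' relieves its own inhibition. The remaining one-way topologies are STI when
#' the F-to-B inhibition lands directly on the target tier, SUI otherwise.
#'
#' @param top An `"ms_topology"`.
#' @return One of `"STI"`, `"SUI"`, `"CFF"`, `"CIPF"`.
#' @export
classify_topology <- function(top) {
  stopifnot(inherits(top, "ms_topology"))
  cycle_b <- top$bf_source_tier >= top$fb_target_tier
  cycle_f <- top$fb_source_tier >= top$bf_target_tier
  if (cycle_b && cycle_f) return("CIPF")
  if (cycle_f) return("CFF")           # no cycle (cycle_b FALSE), but B->F
                                       # link feeds back into the inhibitor
  if (top$fb_target_tier == 2L) "STI" else "SUI"
}

#' Enumerate all 81 cross-inhibition topologies
#'
#' All `3^4` combinations of source and target tiers for the two links, in
#' lexicographic order of `(fb_source_tier, fb_target_tier, bf_source_tier,
#' bf_target_tier)`, each classified into STI/SUI/CFF/CIPF. The class counts
#' are 9/18/18/36.
#'
#' @return A data.frame with columns `id`, the four tier indices and
#'   `class_label`; attribute `"topologies"` holds the list of
#'   `"ms_topology"` objects in the same order.
#' @export
enumerate_topologies <- function() {
  grid <- expand.grid(bf_target_tier = 0:2, bf_source_tier = 0:2,
                      fb_target_tier = 0:2, fb_source_tier = 0:2)
  grid <- grid[, c("fb_source_tier", "fb_target_tier",
                   "bf_source_tier", "bf_target_tier")]
  grid <- grid[order(grid$fb_source_tier, grid$fb_target_tier,
                     grid$bf_source_tier, grid$bf_target_tier), ]
  rownames(grid) <- NULL
  tops <- lapply(seq_len(nrow(grid)), function(i)
    topology(grid$fb_source_tier[i], grid$fb_target_tier[i],
             grid$bf_source_tier[i], grid$bf_target_tier[i]))
  out <- cbind(id = seq_len(nrow(grid)), grid,
               class_label = vapply(tops, `[[`, "", "class_label"))
  attr(out, "topologies") <- tops
  out
}
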