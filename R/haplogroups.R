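# mismatch count between two coded sequences over comparable sites;
# returns c(overlap, mismatches)
compare_codes <- function(xi, xj) {
  ok <- !is.na(xi) & !is.na(xj)
  c(sum(ok), sum(xi[ok] != xj[ok]))
}

#' Cluster variable-length sequences into haplogroups
#'
#' Groups aligned sequences such that members of distinct haplogroups differ
#' at one or more variable sites within shared coverage ("diagnostic sites"),
#' while sequences identical over their (possibly short) coverage fall in the
#' same group. The procedure is greedy and deterministic: sequences are
#' processed longest-coverage first (ties broken by label), and each sequence
#' is compared to every existing haplogroup representative over the columns
#' where both carry an unambiguous base:
#'
#' * at least one mismatch with every representative it overlaps: the
#'   sequence founds a new haplogroup;
#' * zero mismatches with exactly one representative: it joins that group;
#' * zero mismatches with several representatives: the sequence is flagged
#'   ambiguous and assigned to all compatible groups as a candidate only —
#'   it does not become a member and never influences a representative.
#'
#' Because processing is longest-first, the representative of each group is
#' its founding (longest) member, so representatives always carry maximal
#' information. Ambiguity arises exactly when a short fragment misses all
#' columns that discriminate between two or more groups; such fragments are
#' carried forward as alternative hypotheses rather than forced into one
#' group.
#'
#' @param aln A [partial_alignment].
#' @return A `haplogroup_partition`: list with `haplogroups` (each a list of
#'   `id`, `members`, `representative`, `diagnostic_sites` — 0-based columns
#'   at which the representative differs from every other comparable
#'   representative) and `assignments` (named list mapping each sequence
#'   label to its character vector of candidate haplogroup ids; length 1 =
#'   unambiguous).
#' @export
#' @examples
#' aln <- partial_alignment(c(a = "ACGTACGT", b = "ACGTACGA", c = "ACGT????"))
#' p <- build_haplogroups(aln)
#' lengths(p$assignments)  # 'c' is compatible with both groups
build_haplogroups <- function(aln) {
  stopifnot(inherits(aln, "partial_alignment"))
  codes <- aln_code_matrix(aln)
  covlen <- coverage_length(aln)
  ord <- order(-covlen, aln$labels)

  reps <- integer(0)          # row indices of representatives
  members <- list()           # member label vectors
  assign_to <- vector("list", length(aln$labels))
  names(assign_to) <- aln$labels

  for (i in ord) {
    lab <- aln$labels[i]
    if (length(reps) == 0L) {
      reps <- i
      members <- list(lab)
      assign_to[[lab]] <- 1L
      next
    }
    cmp <- vapply(reps, function(r) compare_codes(codes[i, ], codes[r, ]),
                  numeric(2))
    overlapping <- cmp[1L, ] > 0
    if (!any(overlapping))
      stop_format("sequence '%s' has no comparable overlap with any haplogroup representative",
                  lab)
    compatible <- which(overlapping & cmp[2L, ] == 0)
    if (length(compatible) == 0L) {
      reps <- c(reps, i)
      members <- c(members, list(lab))
      assign_to[[lab]] <- length(reps)
    } else if (length(compatible) == 1L) {
      members[[compatible]] <- c(members[[compatible]], lab)
      assign_to[[lab]] <- compatible
    } else {
      assign_to[[lab]] <- compatible  # ambiguous: candidate only
    }
  }

  k <- length(reps)
  ids <- sprintf("HG%02d", seq_len(k))
  rep_codes <- codes[reps, , drop = FALSE]

  diagnostic <- lapply(seq_len(k), function(g) {
    if (k == 1L) return(integer(0))
    here <- !is.na(rep_codes[g, ])
    others <- rep_codes[-g, , drop = FALSE]
    comp <- !is.na(others)
    any_comp <- colSums(comp) > 0
    all_diff <- colSums(comp & (others == rep(rep_codes[g, ], each = k - 1L))) == 0
    which(here & any_comp & all_diff) - 1L  # 0-based columns
  })

  haplogroups <- lapply(seq_len(k), function(g) {
    mem <- members[[g]]
    list(id = ids[g], members = mem, representative = aln$labels[reps[g]],
         diagnostic_sites = diagnostic[[g]])
  })
  assignments <- lapply(assign_to, function(ix) ids[ix])

  structure(list(haplogroups = haplogroups, assignments = assignments),
            class = "haplogroup_partition")
}

#' @export
print.haplogroup_partition <- function(x, ...) {
  amb <- sum(lengths(x$assignments) > 1L)
  cat(sprintf("haplogroup_partition: %d haplogroups, %d sequences (%d ambiguous)\n",
              length(x$haplogroups), length(x$assignments), amb))
  invisible(x)
}

#' Tabulate a haplogroup partition
#'
#' @param part A `haplogroup_partition`.
#' @return Data frame with one row per haplogroup: id, representative,
#'   member count, members (comma separated), candidate-only sequences.
#' @export
haplogroup_table <- function(part) {
  stopifnot(inherits(part, "haplogroup_partition"))
  amb <- names(part$assignments)[lengths(part$assignments) > 1L]
  rows <- lapply(part$haplogroups, function(h) {
    cand <- amb[vapply(part$assignments[amb],
                       function(a) h$id %in% a, logical(1))]
    data.frame(haplogroup = h$id, representative = h$representative,
               n_members = length(h$members),
               members = paste(h$members, collapse = ","),
               candidates_only = paste(cand, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assign haplogroups to species by nearest labeled reference
#'
#' Labels each haplogroup representative with the species of its nearest
#' reference sequence under the TN93 distance, a distance-based surrogate for
#' phylogenetic placement among described taxa. References must share the
#' query alignment's coordinate system. Representatives further than
#' `threshold` from every reference are reported `"unassigned"`.
#'
#' @param part A `haplogroup_partition` built from `aln`.
#' @param aln The [partial_alignment] the partition was built from.
#' @param refs A [partial_alignment] of reference sequences on the same
#'   coordinate system.
#' @param species Named character vector mapping each reference label to its
#'   species name.
#' @param threshold Maximum TN93 distance (substitutions/site) for an
#'   assignment; default 0.10.
#' @return Data frame with columns `haplogroup`, `species`, `distance`.
#'   Ties between species at the minimum distance are broken by the smaller
#'   mean distance to all references of each tied species (and reported via
#'   a message).
#' @export
assign_species <- function(part, aln, refs, species, threshold = 0.10) {
  stopifnot(inherits(part, "haplogroup_partition"),
            inherits(aln, "partial_alignment"),
            inherits(refs, "partial_alignment"))
  if (aln$columns != refs$columns)
    stop_format("query alignment (%d columns) and references (%d columns) are not on the same coordinate system",
                aln$columns, refs$columns)
  if (is.null(names(species)) || !all(refs$labels %in% names(species)))
    stop_format("`species` must be named with every reference label")
  qcodes <- aln_code_matrix(aln)
  rcodes <- aln_code_matrix(refs)

  rows <- lapply(part$haplogroups, function(h) {
    qi <- qcodes[match(h$representative, aln$labels), ]
    dvec <- vapply(seq_along(refs$labels), function(r) {
      st <- pair_stats_codes(qi, rcodes[r, ])
      if (is.null(st)) return(NA_real_)
      suppressWarnings(tn93_distance(st))
    }, numeric(1))
    if (all(is.na(dvec))) {
      warning(sprintf("haplogroup %s has no comparable overlap with any reference",
                      h$id), call. = FALSE)
      return(data.frame(haplogroup = h$id, species = "unassigned",
                        distance = NA_real_, stringsAsFactors = FALSE))
    }
    dmin <- min(dvec, na.rm = TRUE)
    if (dmin > threshold)
      return(data.frame(haplogroup = h$id, species = "unassigned",
                        distance = dmin, stringsAsFactors = FALSE))
    sp_at_min <- unique(species[refs$labels[which(!is.na(dvec) & dvec <= dmin + 1e-12)]])
    if (length(sp_at_min) > 1L) {
      mean_by_sp <- vapply(sp_at_min, function(s)
        mean(dvec[species[refs$labels] == s], na.rm = TRUE), numeric(1))
      message(sprintf("haplogroup %s equidistant from %s; choosing %s by mean reference distance",
                      h$id, paste(sp_at_min, collapse = ", "),
                      sp_at_min[which.min(mean_by_sp)]))
      sp_at_min <- sp_at_min[which.min(mean_by_sp)]
    }
    data.frame(haplogroup = h$id, species = unname(sp_at_min),
               distance = dmin, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
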