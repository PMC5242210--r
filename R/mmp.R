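#' Size constraints for matched molecular pairs
#'
#' Transformation-size restrictions that limit MMPs to pairs of typical
#' analogs: the exchanged substituents may have at most
#' `max_substituent_heavy_atoms` non-hydrogen atoms (default 13, i.e. up to
#' a condensed two-ring system with no more than three additional atoms),
#' and the conserved core must be at least `core_to_substituent_ratio` times
#' (default 2) the size of the larger of the two substituents.
#'
#' @param max_substituent_heavy_atoms cap on substituent heavy atoms.
#' @param core_to_substituent_ratio minimum core size as a multiple of the
#'   larger exchanged substituent.
#' @return list of class `mmp_constraints`.
#' @export
mmp_constraints <- function(max_substituent_heavy_atoms = 13L,
                            core_to_substituent_ratio = 2) {
  stopifnot(max_substituent_heavy_atoms >= 1L, core_to_substituent_ratio > 0)
  structure(list(max_substituent_heavy_atoms =
                   as.integer(max_substituent_heavy_atoms),
                 core_to_substituent_ratio = core_to_substituent_ratio),
            class = "mmp_constraints")
}

#' Test MMP size constraints
#'
#' Vectorized over the three heavy-atom counts: TRUE iff the larger
#' substituent is within the cap and the core is at least the required
#' multiple of that larger substituent.
#'
#' @param core_ha,sub_a_ha,sub_b_ha heavy-atom counts.
#' @param constraints an [mmp_constraints()].
#' @return logical vector.
#' @examples
#' check_constraints(8, 2, 3)    # TRUE:  3 <= 13 and 8 >= 6
#' check_constraints(8, 2, 6)    # FALSE: core 8 < 2 * 6
#' check_constraints(30, 13, 14) # FALSE: 14 exceeds the 13-atom cap
#' @export
check_constraints <- function(core_ha, sub_a_ha, sub_b_ha,
                              constraints = mmp_constraints()) {
  stopifnot(inherits(constraints, "mmp_constraints"))
  larger <- pmax(sub_a_ha, sub_b_ha)
  larger <= constraints$max_substituent_heavy_atoms &
    core_ha >= constraints$core_to_substituent_ratio * larger
}

empty_mmp_table <- function() {
  data.frame(compound_a = character(), compound_b = character(),
             core = character(), core_ha = integer(),
             sub_a = character(), sub_a_ha = integer(),
             sub_b = character(), sub_b_ha = integer(),
             rule_id = character(), stringsAsFactors = FALSE)
}

#' Generate size-constrained RECAP matched molecular pairs
#'
#' Core-indexing algorithm: fragment pairs are grouped by exact canonical
#' core string, and every unordered pair of parents within a group whose
#' substituents differ and satisfy [check_constraints()] becomes an MMP.
#' This is equivalent to comparing all compound pairs directly (two
#' compounds form an MMP for a core iff both yield that exact core from a
#' single retrosynthetic cut) but scales with the number of fragment pairs.
#' A compound pair sharing several distinct cores yields one MMP record per
#' core. Output is deterministically ordered and `compound_a < compound_b`
#' within each record.
#'
#' @param fragments fragment-pair table from [enumerate_recap_cuts()], built
#'   over canonical, deduplicated compounds.
#' @param constraints an [mmp_constraints()].
#' @return data.frame with columns `compound_a`, `compound_b`, `core`,
#'   `core_ha`, `sub_a`, `sub_a_ha`, `sub_b`, `sub_b_ha`, `rule_id`.
#' @export
generate_mmps <- function(fragments, constraints = mmp_constraints()) {
  stopifnot(inherits(constraints, "mmp_constraints"))
  if (nrow(fragments) == 0L) return(empty_mmp_table())

  ## necessary per-fragment conditions (the pairwise max can only be larger)
  f <- fragments[fragments$sub_ha <= constraints$max_substituent_heavy_atoms &
                   fragments$core_ha >=
                     constraints$core_to_substituent_ratio * fragments$sub_ha, ,
                 drop = FALSE]
  if (nrow(f) == 0L) return(empty_mmp_table())
  f <- f[!duplicated(paste(f$parent_id, f$core, sep = "\r")), , drop = FALSE]

  groups <- split(seq_len(nrow(f)), f$core)
  groups <- groups[lengths(groups) >= 2L]
  out <- lapply(groups, function(idx) {
    idx <- idx[order(f$parent_id[idx])]
    k <- length(idx)
    pair <- utils::combn(k, 2L)
    i <- idx[pair[1L, ]]
    j <- idx[pair[2L, ]]
    ok <- f$sub[i] != f$sub[j] &
      check_constraints(f$core_ha[i], f$sub_ha[i], f$sub_ha[j], constraints)
    i <- i[ok]; j <- j[ok]
    if (!length(i)) return(NULL)
    data.frame(compound_a = f$parent_id[i], compound_b = f$parent_id[j],
               core = f$core[i], core_ha = f$core_ha[i],
               sub_a = f$sub[i], sub_a_ha = f$sub_ha[i],
               sub_b = f$sub[j], sub_b_ha = f$sub_ha[j],
               rule_id = f$rule_id[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) return(empty_mmp_table())
  out <- out[order(out$compound_a, out$compound_b, out$core), , drop = FALSE]
  rownames(out) <- NULL
  out
}
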