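#' Canonicalize SMILES strings
#'
#' Maps every input to a deterministic canonical SMILES so that two notations
#' of the same chemical graph compare equal as strings. Multi-component
#' inputs (salts, mixtures) are stripped to their largest covalent component
#' and the strip is reported. Stereochemistry is preserved: two stereoisomers
#' remain distinct compounds. Unparseable inputs are returned with an error
#' code rather than aborting the batch.
#'
#' @param smiles character vector of SMILES. Attachment points (`*` or `[*]`)
#'   are allowed, so fragments can be canonicalized with the same function;
#'   the wildcard atom is never counted as a heavy atom.
#' @return data.frame with one row per input: `input`, `canonical` (empty
#'   string on failure), `heavy_atoms`, `n_stripped` (components removed by
#'   salt stripping) and `error` (empty string when clean).
#' @examples
#' \dontrun{
#' canonicalize(c("C(C)N", "CCN"))$canonical  # identical strings
#' }
#' @export
canonicalize <- function(smiles) {
  if (length(smiles) == 0L) {
    return(data.frame(input = character(), canonical = character(),
                      heavy_atoms = integer(), n_stripped = integer(),
                      error = character(), stringsAsFactors = FALSE))
  }
  out <- run_bridge("canon", data.frame(id = seq_along(smiles),
                                        smiles = smiles,
                                        stringsAsFactors = FALSE))
  data.frame(input = smiles,
             canonical = as.character(out$canonical),
             heavy_atoms = as.integer(out$heavy_atoms),
             n_stripped = as.integer(out$n_stripped),
             error = as.character(out$error),
             stringsAsFactors = FALSE)
}

#' Canonical SMILES as a plain vector
#'
#' Convenience wrapper around [canonicalize()]; parse failures become `NA`.
#'
#' @inheritParams canonicalize
#' @return character vector of canonical SMILES, `NA` where parsing failed.
#' @export
canonical_smiles <- function(smiles) {
  res <- canonicalize(smiles)
  ifelse(nzchar(res$error), NA_character_, res$canonical)
}

#' Count non-hydrogen atoms of fragments or molecules
#'
#' Heavy atoms are all non-hydrogen atoms; the attachment-point wildcard is
#' not counted.
#'
#' @param smiles character vector of SMILES (with or without an attachment
#'   point).
#' @return integer vector; `NA` where parsing failed.
#' @export
count_heavy_atoms <- function(smiles) {
  res <- canonicalize(smiles)
  ifelse(nzchar(res$error), NA_integer_, res$heavy_atoms)
}

#' Retrosynthetic (RECAP) bond-cut rules
#'
#' Loads the bond-matching rule table used for fragmentation. The default
#' table encodes the eleven RECAP bond types (amide, ester, amine, urea,
#' ether, olefin, quaternary nitrogen, aromatic N--aliphatic C, lactam
#' N--aliphatic C, aromatic C--aromatic C, sulfonamide) as SMARTS patterns
#' whose atoms mapped `:1` and `:2` flank the bond to cut. Only acyclic
#' bonds are ever cut; file order is the priority used when several rules
#' match the same bond. RECAP dialects differ between toolkits, so the table
#' is deliberately a plain file that can be audited, edited or replaced. The
#' default dialect cuts acyclic bonds between two aromatic-ring carbons even
#' when the rings belong to different fused systems.
#'
#' @param path path to a rules TSV with columns `rule_id`, `name`, `smarts`;
#'   default: the table shipped with the package.
#' @return data.frame with columns `rule_id`, `name`, `smarts` and
#'   attribute `path` (passed on to the fragmentation backend).
#' @export
recap_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "recap_rules.tsv",
                        package = "asbscaffold", mustWork = TRUE)
  }
  rules <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("rule_id", "smarts") %in% names(rules)))
  attr(rules, "path") <- path
  rules
}

#' Enumerate single-cut retrosynthetic fragment pairs
#'
#' Cuts every distinct acyclic bond of every compound that matches a RECAP
#' rule, yielding fragment pairs in both orientations (each side once as
#' core, once as substituent, both carrying one attachment point).
#' Duplicate pairs arising from molecular symmetry are collapsed. Ring bonds
#' are never cut, and molecules with no matching bond simply contribute no
#' rows. Only single cuts are performed: an MMP here is defined by a
#' modification at exactly one site.
#'
#' @param compounds data.frame with columns `compound_id` and `smiles`
#'   (canonical SMILES; see [canonicalize()]).
#' @param rules rule table from [recap_rules()].
#' @return data.frame with columns `parent_id`, `rule_id`, `core`, `core_ha`,
#'   `sub`, `sub_ha`. Core and substituent are canonical fragment SMILES with
#'   one wildcard attachment point; heavy-atom counts exclude the wildcard.
#' @export
enumerate_recap_cuts <- function(compounds, rules = recap_rules()) {
  stopifnot(all(c("compound_id", "smiles") %in% names(compounds)))
  empty <- data.frame(parent_id = character(), rule_id = character(),
                      core = character(), core_ha = integer(),
                      sub = character(), sub_ha = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(compounds) == 0L) return(empty)
  rules_path <- attr(rules, "path")
  if (is.null(rules_path)) {
    rules_path <- tempfile(fileext = ".tsv")
    on.exit(unlink(rules_path), add = TRUE)
    write_bridge_tsv(rules, rules_path)
  }
  out <- run_bridge("frag",
                    data.frame(id = compounds$compound_id,
                               smiles = compounds$smiles,
                               stringsAsFactors = FALSE),
                    rules_path = rules_path)
  if (nrow(out) == 0L) return(empty)
  data.frame(parent_id = as.character(out$parent_id),
             rule_id = as.character(out$rule_id),
             core = as.character(out$core),
             core_ha = as.integer(out$core_ha),
             sub = as.character(out$sub),
             sub_ha = as.integer(out$sub_ha),
             stringsAsFactors = FALSE)
}

#' Reassemble a fragment pair into its parent molecule
#'
#' Joins a core and a substituent at their attachment points and returns the
#' canonical SMILES of the result. Used for round-trip validation: every
#' fragment pair must reassemble to its parent, and every ASB scaffold plus
#' a member's substituent must reassemble to that member.
#'
#' @param core,sub character vectors of fragment SMILES, each with exactly
#'   one attachment point; recycled to common length.
#' @return character vector of canonical SMILES; `NA` where joining failed.
#' @export
reassemble_fragments <- function(core, sub) {
  n <- max(length(core), length(sub))
  core <- rep_len(core, n)
  sub <- rep_len(sub, n)
  if (n == 0L) return(character())
  out <- run_bridge("join", data.frame(id = seq_len(n), core = core, sub = sub,
                                       stringsAsFactors = FALSE))
  ifelse(nzchar(as.character(out$error)), NA_character_,
         as.character(out$smiles))
}
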