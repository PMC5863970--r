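#' Construct and validate a ligand descriptor table
#'
#' A ligand table holds one row per compound with its physicochemical
#' descriptors. Required: `id` (unique), `mw_da`, `n_hba`, `n_hbd`, `logp`.
#' Recognised optional columns: `tpsa_a2`, `nha` (heavy-atom count),
#' `n_polar` (N+O count), `n_tdof`, `n_rot`, `n_rb`, `formal_charge`,
#' `pubchem_cid`. Other columns are carried through untouched.
#'
#' Invariants enforced where the fields are present: `mw_da > 0`, counts
#' non-negative, `n_polar <= nha`, `tpsa_a2 >= 0`.
#'
#' @param x A data frame of descriptors, one row per ligand.
#' @return `x` with class `c("ligand_table", "data.frame")`.
#' @examples
#' lig <- as_ligand_table(data.frame(
#'   id = "BBR", mw_da = 336.36, n_hba = 4, n_hbd = 0, logp = 2.473,
#'   nha = 25, n_polar = 5))
#' @export
as_ligand_table <- function(x) {
  if (!is.data.frame(x)) stop("`x` must be a data frame", call. = FALSE)
  required <- c("id", "mw_da", "n_hba", "n_hbd", "logp")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stop("missing required descriptor column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x$id <- as.character(x$id)
  if (anyDuplicated(x$id)) {
    stop("duplicate ligand id(s): ",
         paste(unique(x$id[duplicated(x$id)]), collapse = ", "), call. = FALSE)
  }
  numeric_cols <- intersect(
    c("mw_da", "n_hba", "n_hbd", "logp", "tpsa_a2", "nha", "n_polar",
      "n_tdof", "n_rot", "n_rb", "formal_charge"), names(x))
  for (cl in numeric_cols) {
    if (!is.numeric(x[[cl]])) {
      stop("descriptor column `", cl, "` must be numeric", call. = FALSE)
    }
  }
  if (nrow(x)) {
    if (any(!is.na(x$mw_da) & x$mw_da <= 0)) {
      stop("`mw_da` must be positive", call. = FALSE)
    }
    counts <- intersect(c("n_hba", "n_hbd", "nha", "n_polar", "n_tdof",
                          "n_rot", "n_rb"), names(x))
    for (cl in counts) {
      if (any(!is.na(x[[cl]]) & x[[cl]] < 0)) {
        stop("`", cl, "` must be non-negative", call. = FALSE)
      }
    }
    if (all(c("n_polar", "nha") %in% names(x))) {
      bad <- !is.na(x$n_polar) & !is.na(x$nha) & x$n_polar > x$nha
      if (any(bad)) {
        stop("`n_polar` exceeds `nha` for ligand(s): ",
             paste(x$id[bad], collapse = ", "), call. = FALSE)
      }
    }
    if ("tpsa_a2" %in% names(x) && any(!is.na(x$tpsa_a2) & x$tpsa_a2 < 0)) {
      stop("`tpsa_a2` must be non-negative", call. = FALSE)
    }
  }
  class(x) <- unique(c("ligand_table", class(x)))
  x
}

# rule thresholds of the classical rule of five
.lipinski_rules <- list(
  mw   = list(field = "mw_da", max = 500),
  logp = list(field = "logp",  max = 5),
  hbd  = list(field = "n_hbd", max = 5),
  hba  = list(field = "n_hba", max = 10)
)

#' Lipinski rule-of-five check
#'
#' Evaluates the four classical drug-likeness rules — MW <= 500 Da,
#' LogP <= 5, H-bond donors <= 5, H-bond acceptors <= 10 — for each ligand.
#' The default policy is strict: a ligand passes only with zero violations.
#'
#' @param ligands A [as_ligand_table()] (or coercible data frame).
#' @param max_violations Number of tolerated rule violations (0 = strict;
#'   1 reproduces the common "one violation allowed" reading).
#' @return A data frame with one row per ligand: `ligand_id`, `passed`,
#'   `n_violations`, and `violations` (comma-separated rule ids among
#'   `mw`, `logp`, `hbd`, `hba`; empty string when none).
#' @examples
#' tabs <- berberine_raf_tables()
#' lipinski_check(tabs$ligands)
#' @export
lipinski_check <- function(ligands, max_violations = 0) {
  ligands <- as_ligand_table(as.data.frame(ligands))
  stopifnot(is.numeric(max_violations), length(max_violations) == 1L,
            max_violations >= 0)
  for (rule in names(.lipinski_rules)) {
    fld <- .lipinski_rules[[rule]]$field
    if (any(is.na(ligands[[fld]]))) {
      stop("descriptor `", fld, "` is missing for ligand(s): ",
           paste(ligands$id[is.na(ligands[[fld]])], collapse = ", "),
           call. = FALSE)
    }
  }
  viol <- vapply(seq_len(nrow(ligands)), function(i) {
    broken <- vapply(names(.lipinski_rules), function(rule) {
      spec <- .lipinski_rules[[rule]]
      ligands[[spec$field]][i] > spec$max
    }, logical(1))
    paste(names(.lipinski_rules)[broken], collapse = ",")
  }, character(1))
  n_viol <- ifelse(nzchar(viol), lengths(strsplit(viol, ",", fixed = TRUE)), 0L)
  data.frame(
    ligand_id = ligands$id,
    passed = n_viol <= max_violations,
    n_violations = as.integer(n_viol),
    violations = viol,
    stringsAsFactors = FALSE
  )
}

#' Screen a ligand library with the rule of five
#'
#' Partitions a library into passing and failing subsets, preserving input
#' order; every input ligand lands in exactly one subset.
#'
#' @inheritParams lipinski_check
#' @return A list with elements `passing` and `failing` (ligand tables) and
#'   `verdicts` (the [lipinski_check()] output for the full input).
#' @examples
#' tabs <- berberine_raf_tables()
#' scr <- filter_library(tabs$ligands)
#' nrow(scr$passing) # all 12 reference ligands are drug-like
#' @export
filter_library <- function(ligands, max_violations = 0) {
  ligands <- as_ligand_table(as.data.frame(ligands))
  verdicts <- lipinski_check(ligands, max_violations = max_violations)
  keep <- verdicts$passed
  list(
    passing = as_ligand_table(ligands[keep, , drop = FALSE]),
    failing = as_ligand_table(ligands[!keep, , drop = FALSE]),
    verdicts = verdicts
  )
}
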