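#' Screening results
#'
#' Every pre-network filter returns a `screening_result`: the kept rows,
#' the rejected rows (kept and rejected partition the input) and a
#' per-item flag table saying which rule failed.
#'
#' @name screening_result
NULL

.screening_result <- function(kept, rejected, flags, filter) {
  structure(list(kept = kept, rejected = rejected, flags = flags, filter = filter),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat("screening_result [", x$filter, "]: kept ", nrow(x$kept),
      ", rejected ", nrow(x$rejected), "\n", sep = "")
  invisible(x)
}

#' Lipinski drug-likeness filter
#'
#' Keeps a compound iff `mw < 500` (strict), `hbd <= 5`, `hba <= 10` and
#' `mlogp <= 5`. The boundary semantics follow the printed rule set
#' exactly: molecular weight uses a strict inequality, the other three
#' are inclusive. A record at MW = 500 is therefore rejected while one
#' at HBD = 5 is kept.
#'
#' @param compounds compound data frame with numeric columns `mw`,
#'   `hbd`, `hba`, `mlogp` (see [read_compound_table()]).
#' @return a `screening_result`; `flags` has one row per compound with
#'   logical columns per criterion and a `violated` string naming the
#'   failed rules.
#' @export
lipinski_filter <- function(compounds) {
  stopifnot(is.data.frame(compounds))
  required <- c("mw", "hbd", "hba", "mlogp")
  missing <- setdiff(required, names(compounds))
  if (length(missing)) stop("compound table is missing column(s): ",
                            paste(missing, collapse = ", "))
  for (col in required) {
    if (!is.numeric(compounds[[col]])) stop("column '", col, "' must be numeric")
    bad <- which(is.na(compounds[[col]]))
    if (length(bad)) {
      id <- if ("compound_id" %in% names(compounds)) compounds$compound_id[bad[1]] else bad[1]
      stop("missing value of '", col, "' for compound ", id)
    }
  }
  mw_ok <- compounds$mw < 500
  hbd_ok <- compounds$hbd <= 5
  hba_ok <- compounds$hba <= 10
  mlogp_ok <- compounds$mlogp <= 5
  pass <- mw_ok & hbd_ok & hba_ok & mlogp_ok
  violated <- apply(cbind(MW = !mw_ok, HBD = !hbd_ok, HBA = !hba_ok, MlogP = !mlogp_ok),
                    1L, function(v) paste(names(v)[v], collapse = ","))
  flags <- data.frame(
    compound_id = if ("compound_id" %in% names(compounds)) compounds$compound_id
                  else as.character(seq_len(nrow(compounds))),
    mw_ok = mw_ok, hbd_ok = hbd_ok, hba_ok = hba_ok, mlogp_ok = mlogp_ok,
    pass = pass, violated = violated, stringsAsFactors = FALSE)
  .screening_result(kept = compounds[pass, , drop = FALSE],
                    rejected = compounds[!pass, , drop = FALSE],
                    flags = flags, filter = "lipinski")
}

#' Minimum-support filter on targets
#'
#' Keeps a target iff it interacts with at least `min_support` distinct
#' compounds; all rows of removed targets go to `rejected`. At the
#' default threshold a target supported by 4 compounds is removed and
#' one supported by 5 is kept.
#'
#' @param interactions interaction data frame (`compound_id`, `target_id`).
#' @param min_support minimum distinct-compound count, default 5.
#' @return a `screening_result` over interaction rows; `flags` has one
#'   row per target with its support and kept status.
#' @export
filter_targets_by_support <- function(interactions, min_support = 5) {
  stopifnot(is.data.frame(interactions),
            all(c("compound_id", "target_id") %in% names(interactions)))
  if (min_support < 1) stop("min_support must be >= 1")
  dedup <- unique(interactions[, c("compound_id", "target_id")])
  support <- tapply(dedup$compound_id, dedup$target_id,
                    function(x) length(unique(x)))
  support <- support[order(names(support))]
  keep_targets <- names(support)[support >= min_support]
  keep_row <- interactions$target_id %in% keep_targets
  flags <- data.frame(target_id = names(support),
                      support = as.integer(support),
                      kept = names(support) %in% keep_targets,
                      stringsAsFactors = FALSE, row.names = NULL)
  .screening_result(kept = interactions[keep_row, , drop = FALSE],
                    rejected = interactions[!keep_row, , drop = FALSE],
                    flags = flags, filter = "target_support")
}

#' Drop compounds without any target
#'
#' After target filtering, compounds retaining at least one interaction
#' row are kept; ingredients without any target protein are excluded.
#'
#' @param interactions (already filtered) interaction data frame.
#' @param compounds compound data frame with `compound_id`.
#' @return a `screening_result` over compound rows.
#' @export
drop_targetless_compounds <- function(interactions, compounds) {
  stopifnot(is.data.frame(compounds), "compound_id" %in% names(compounds))
  with_targets <- unique(as.character(interactions$compound_id))
  keep <- compounds$compound_id %in% with_targets
  flags <- data.frame(compound_id = compounds$compound_id,
                      has_target = keep, stringsAsFactors = FALSE)
  .screening_result(kept = compounds[keep, , drop = FALSE],
                    rejected = compounds[!keep, , drop = FALSE],
                    flags = flags, filter = "targetless_compound")
}

#' Full pre-network screening funnel
#'
#' Applies, in order: the Lipinski filter on compounds, restriction of
#' the interaction table to drug-like compounds, the target
#' minimum-support filter, and removal of targetless compounds. The
#' order is configurable but the default reproduces the narrative
#' screening sequence.
#'
#' @param compounds compound data frame.
#' @param interactions interaction data frame.
#' @param min_support target support threshold (default 5).
#' @param apply_lipinski apply the drug-likeness filter first (default
#'   `TRUE`).
#' @return list with `compounds` (final kept compound table),
#'   `interactions` (final kept interaction table), the three
#'   `screening_result`s, and a `funnel` data frame of stage counts.
#' @export
screen_dataset <- function(compounds, interactions, min_support = 5,
                           apply_lipinski = TRUE) {
  n0 <- nrow(compounds)
  if (apply_lipinski) {
    lip <- lipinski_filter(compounds)
    compounds1 <- lip$kept
  } else {
    lip <- NULL
    compounds1 <- compounds
  }
  interactions1 <- interactions[interactions$compound_id %in% compounds1$compound_id, ,
                                drop = FALSE]
  sup <- filter_targets_by_support(interactions1, min_support = min_support)
  drop <- drop_targetless_compounds(sup$kept, compounds1)
  funnel <- data.frame(
    stage = c("input", "druglike", "with_targets"),
    compounds = c(n0, nrow(compounds1), nrow(drop$kept)),
    targets = c(NA, length(unique(interactions1$target_id)),
                length(unique(sup$kept$target_id))),
    interactions = c(nrow(interactions), nrow(interactions1), nrow(sup$kept)),
    stringsAsFactors = FALSE)
  list(compounds = drop$kept, interactions = sup$kept,
       lipinski = lip, target_support = sup, targetless = drop,
       funnel = funnel)
}
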