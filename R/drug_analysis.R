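# Projection of drug-target tables (DrugBank/ChEMBL-style TSV exports)
# onto similarity groups: shared druggable targets and per-group
# multi-target drug reports.

DRUG_SOURCES <- c("DRUGBANK", "CHEMBL", "OTHER")

#' Load a drug-target table
#'
#' Reads a TSV with columns `drug_id`, `drug_name`, `source_db`,
#' `target_symbol` and optional `evidence`. Target symbols are uppercased
#' and converted to HGNC canonical keys; duplicate (drug, target) pairs
#' collapse to one record with a warning; rows with an empty target are
#' rejected with their row number; unknown source databases map to
#' `OTHER` with a warning.
#'
#' @param path Path to the TSV file.
#' @return `data.frame` of `drug_id`, `drug_name`, `source_db`, `target`
#'   (canonical key), `evidence`.
#' @export
load_drug_targets <- function(path) {
  if (!file.exists(path)) stop("drug-target file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  required <- c("drug_id", "drug_name", "source_db", "target_symbol")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("drug-target table missing column(s): ", paste(missing, collapse = ", "))
  }
  if (is.null(tab$evidence)) tab$evidence <- ""
  empty <- which(!nzchar(trimws(tab$target_symbol)))
  if (length(empty)) {
    warning("rejected row(s) with empty target: ",
            paste(empty, collapse = ", "), call. = FALSE)
    tab <- tab[-empty, , drop = FALSE]
  }
  src <- toupper(trimws(tab$source_db))
  unknown <- !(src %in% DRUG_SOURCES)
  if (any(unknown)) {
    warning("unknown source_db mapped to OTHER: ",
            paste(unique(src[unknown]), collapse = ", "), call. = FALSE)
    src[unknown] <- "OTHER"
  }
  out <- data.frame(drug_id = trimws(tab$drug_id),
                    drug_name = trimws(tab$drug_name),
                    source_db = src,
                    target = paste0("HGNC:", toupper(trimws(tab$target_symbol))),
                    evidence = tab$evidence, stringsAsFactors = FALSE)
  dup <- duplicated(paste(out$drug_id, out$target, sep = "\r"))
  if (any(dup)) {
    warning(sum(dup), " duplicate (drug, target) row(s) collapsed", call. = FALSE)
    out <- out[!dup, , drop = FALSE]
  }
  out <- out[order_c(out$drug_id, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# canonical ids occurring in a group, per map side and combined
group_key_sets <- function(groups, map_a, map_b) {
  lapply(groups, function(g) {
    ka <- interaction_key_sets(map_a, g$scc_a$members)
    kb <- interaction_key_sets(map_b, g$scc_b$members)
    list(group_id = g$group_id, a = ka, b = kb, all = unique(c(ka, kb)))
  })
}

#' Shared druggable targets across the similarity groups
#'
#' Canonical identifiers that appear in the interactions of at least one
#' group on BOTH maps' sides and are the target of at least one
#' drug-target record.
#'
#' @param groups Group list from [pair_components()].
#' @param records Drug-target records from [load_drug_targets()].
#' @param map_a,map_b The compared maps.
#' @return Sorted character vector of canonical keys.
#' @export
shared_drug_targets <- function(groups, records, map_a, map_b) {
  ks <- group_key_sets(groups, map_a, map_b)
  both <- unique(unlist(lapply(ks, function(g) intersect(g$a, g$b))))
  sort_c(intersect(both, unique(records$target)))
}

#' Per-group multi-target drug reports
#'
#' For each similarity group, the drugs hitting at least
#' `min_targets_per_group` distinct targets within that group's
#' interactions ("more than one target per group" at the default of 2).
#'
#' @inheritParams shared_drug_targets
#' @param min_targets_per_group Minimum distinct targets a drug must hit
#'   inside a group to be reported there.
#' @return List of reports, one per group with at least one qualifying
#'   drug: `group_id`, `targets_in_group` (druggable keys present in the
#'   group), `drugs` (`data.frame` of `drug_id`, `drug_name`, `n_targets`,
#'   `targets` comma-joined).
#' @export
group_drug_reports <- function(groups, records, map_a, map_b,
                               min_targets_per_group = 2) {
  ks <- group_key_sets(groups, map_a, map_b)
  out <- list()
  for (g in ks) {
    hit <- records[records$target %in% g$all, , drop = FALSE]
    if (nrow(hit) == 0) next
    per_drug <- split(hit, hit$drug_id)
    rows <- list()
    for (d in names(per_drug)) {
      tg <- sort_c(unique(per_drug[[d]]$target))
      if (length(tg) < min_targets_per_group) next
      rows[[length(rows) + 1L]] <- data.frame(
        drug_id = d, drug_name = per_drug[[d]]$drug_name[1],
        n_targets = length(tg), targets = paste(tg, collapse = ","),
        stringsAsFactors = FALSE)
    }
    if (length(rows) == 0) next
    drugs <- do.call(rbind, rows)
    drugs <- drugs[order_c(-drugs$n_targets, drugs$drug_id), , drop = FALSE]
    rownames(drugs) <- NULL
    # contract: every reported pair is witnessed by enough records in-group
    stopifnot(all(drugs$n_targets >= min_targets_per_group))
    out[[length(out) + 1L]] <- list(
      group_id = g$group_id,
      targets_in_group = sort_c(intersect(g$all, unique(records$target))),
      drugs = drugs)
  }
  out
}
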