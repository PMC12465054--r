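# MINERVA-dialect data overlays: qualitative variant-presence overlays and
# differential-expression overlays with log fold changes scaled to [-1, 1].

VARIANT_COLOR <- "#0000FF"

#' Build a variant-presence overlay
#'
#' A qualitative overlay marking genes affected by at least one disease
#' associated variant: one entry per distinct symbol, value 1, a fixed
#' highlight colour. Symbols are trimmed and uppercased.
#'
#' @param gene_list Non-empty character vector of HGNC symbols.
#' @param name Overlay name.
#' @param color Hex colour for all entries.
#' @return Object of class `map_overlay`.
#' @export
variant_overlay <- function(gene_list, name, color = VARIANT_COLOR) {
  gene_list <- toupper(trimws(as.character(gene_list)))
  gene_list <- unique(gene_list[nzchar(gene_list)])
  if (length(gene_list) == 0) stop("variant_overlay: empty gene list")
  gene_list <- sort_c(gene_list)
  new_overlay(name, "GENETIC_VARIANT",
              data.frame(name = gene_list, value = 1, color = color,
                         stringsAsFactors = FALSE))
}

#' Scale log fold changes to [-1, 1]
#'
#' Max-absolute scaling: every value is divided by the largest absolute
#' value in the dataset, preserving sign, zero, and the ordering of
#' magnitudes (min-max scaling would not). An all-zero input stays all
#' zero; non-finite values are dropped with a warning.
#'
#' @param symbols Character vector of gene symbols.
#' @param lfc Numeric vector of log fold changes (same length).
#' @return `data.frame` of `symbol`, `scaled`, all values within [-1, 1].
#' @export
scale_log_fold_changes <- function(symbols, lfc) {
  stopifnot(length(symbols) == length(lfc))
  ok <- is.finite(lfc)
  if (!all(ok)) {
    warning(sum(!ok), " non-finite value(s) dropped", call. = FALSE)
    symbols <- symbols[ok]; lfc <- lfc[ok]
  }
  if (length(lfc) == 0) stop("no finite values to scale")
  m <- max(abs(lfc))
  scaled <- if (m == 0) lfc else lfc / m
  data.frame(symbol = as.character(symbols), scaled = scaled,
             stringsAsFactors = FALSE)
}

#' Build a differential-expression overlay
#'
#' Scales log fold changes with [scale_log_fold_changes()] and assembles a
#' `map_overlay`. Duplicate symbols are aggregated by the value of largest
#' magnitude (the strongest signal), with a warning.
#'
#' @inheritParams scale_log_fold_changes
#' @param name Overlay name.
#' @return Object of class `map_overlay`.
#' @export
expression_overlay <- function(symbols, lfc, name) {
  symbols <- toupper(trimws(as.character(symbols)))
  if (anyDuplicated(symbols)) {
    warning("duplicate symbols aggregated by largest-magnitude value",
            call. = FALSE)
    keep <- vapply(split(seq_along(symbols), symbols),
                   function(ix) ix[which.max(abs(lfc[ix]))], 0L)
    symbols <- symbols[keep]; lfc <- lfc[keep]
  }
  sc <- scale_log_fold_changes(symbols, lfc)
  ord <- order_c(sc$symbol)
  new_overlay(name, "EXPRESSION",
              data.frame(name = sc$symbol[ord], value = sc$scaled[ord],
                         stringsAsFactors = FALSE))
}

new_overlay <- function(name, type_tag, entries) {
  stopifnot(is.data.frame(entries), all(c("name", "value") %in% names(entries)))
  if (any(!nzchar(entries$name))) stop("overlay entry with empty identifier")
  if (anyDuplicated(entries$name)) stop("duplicate identifiers in overlay")
  structure(list(name = name, type_tag = type_tag, entries = entries),
            class = "map_overlay")
}

#' Write a data overlay file
#'
#' MINERVA-dialect TSV: two comment header lines `#NAME=` and `#TYPE=`,
#' a column header (`name`, `value`, optionally `color`), then one row per
#' entry. Values are checked to lie within [-1, 1] — out-of-range values
#' indicate unscaled input and are a fatal error. Output is byte-stable.
#'
#' @param o A `map_overlay`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_overlay <- function(o, path) {
  stopifnot(inherits(o, "map_overlay"))
  v <- o$entries$value
  if (any(v < -1 | v > 1)) {
    stop("overlay value out of [-1, 1]: ", paste(v[v < -1 | v > 1], collapse = ", "),
         " (scale the input first)")
  }
  has_color <- "color" %in% names(o$entries)
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- c(paste0("#NAME=", o$name), paste0("#TYPE=", o$type_tag),
             if (has_color) "name\tvalue\tcolor" else "name\tvalue")
  rows <- if (has_color) {
    sprintf("%s\t%s\t%s", o$entries$name, format_value(v), o$entries$color)
  } else {
    sprintf("%s\t%s", o$entries$name, format_value(v))
  }
  writeLines(c(lines, rows), con = con, useBytes = TRUE)
  invisible(path)
}

# fixed-notation, trailing-zero-free numeric formatting for stable files
format_value <- function(x) {
  s <- sprintf("%.10f", x)
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}

#' Read a data overlay file
#'
#' Inverse of [write_overlay()].
#'
#' @param path Path to an overlay TSV.
#' @return Object of class `map_overlay`.
#' @export
read_overlay <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  header <- grep("^#", lines, value = TRUE)
  get_tag <- function(tag) {
    hit <- grep(paste0("^#", tag, "="), header, value = TRUE)
    if (length(hit) == 0) "" else sub(paste0("^#", tag, "="), "", hit[1])
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (length(body) < 1) stop("overlay file has no column header: ", path)
  cols <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  entries <- data.frame(
    name = vapply(rows, `[[`, "", 1),
    value = as.numeric(vapply(rows, `[[`, "", 2)),
    stringsAsFactors = FALSE)
  if ("color" %in% cols) entries$color <- vapply(rows, `[[`, "", 3)
  new_overlay(get_tag("NAME"), get_tag("TYPE"), entries)
}
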