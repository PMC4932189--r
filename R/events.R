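#' Recognised dispersal directions
#'
#' Dispersal between the Indian subcontinent and mainland Asia is coded as one
#' of two directions.
#'
#' @return Character vector of the two valid direction labels.
#' @export
mde_directions <- function() c("india_to_asia", "asia_to_india")

#' Recognised taxon groups
#'
#' The taxon groups used to stratify dispersal events. `bird` is singled out by
#' the sampling-bias correction ([avian_bias_cutoff()]); all other groups count
#' as non-avian.
#'
#' @return Character vector of the eight valid taxon-group labels.
#' @export
mde_taxa <- function() {
  c("amphibian", "non_avian_reptile", "bird", "arthropod",
    "plant", "teleost_fish", "mammal", "other")
}

.event_cols <- c("event_id", "dataset_id", "taxon_group", "direction",
                 "hpd_old_ma", "hpd_young_ma")

#' Construct a dispersal-event table
#'
#' An event table holds one row per inferred dispersal/range-shift event: an
#' opaque unique `event_id`, the `dataset_id` of the source phylogeny, a
#' `taxon_group` (see [mde_taxa()]), a `direction` (see [mde_directions()]),
#' and the older/younger bounds of the 95% HPD interval of the divergence time
#' (Ma) at the node where the range shift was inferred. Events from the same
#' source phylogeny are deliberately kept as independent rows.
#'
#' @param event_id character, unique per row.
#' @param dataset_id character, source phylogeny identifier.
#' @param taxon_group character, values from [mde_taxa()].
#' @param direction character, values from [mde_directions()].
#' @param hpd_old_ma numeric, older HPD bound in Ma.
#' @param hpd_young_ma numeric, younger HPD bound in Ma; `hpd_old_ma >=
#'   hpd_young_ma >= 0` is enforced.
#' @param metadata optional named list of free-form provenance.
#'
#' @return A data frame of class `event_table`.
#' @examples
#' event_table(event_id = c("e1", "e2"), dataset_id = "ds1",
#'             taxon_group = "plant", direction = "asia_to_india",
#'             hpd_old_ma = c(12.4, 33.0), hpd_young_ma = c(4.1, 21.7))
#' @export
event_table <- function(event_id = character(), dataset_id = character(),
                        taxon_group = character(), direction = character(),
                        hpd_old_ma = numeric(), hpd_young_ma = numeric(),
                        metadata = list()) {
  df <- data.frame(
    event_id = as.character(event_id),
    dataset_id = as.character(dataset_id),
    taxon_group = as.character(taxon_group),
    direction = as.character(direction),
    hpd_old_ma = as.numeric(hpd_old_ma),
    hpd_young_ma = as.numeric(hpd_young_ma),
    stringsAsFactors = FALSE
  )
  validate_events(df)
  structure(df, class = c("event_table", "data.frame"), metadata = metadata)
}

#' Validate an event table
#'
#' Checks the six-column schema and all per-event invariants; errors name the
#' offending row and field. Unknown direction or taxon labels are rejected
#' rather than coerced, since silent coercion would corrupt the avian/non-avian
#' pooling used for bias correction.
#'
#' @param df data frame with the event-table columns.
#' @return `df`, invisibly, if valid.
#' @export
validate_events <- function(df) {
  missing <- setdiff(.event_cols, names(df))
  if (length(missing)) {
    stop("event table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0L) return(invisible(df))

  bad_field <- function(i, field, why) {
    stop(sprintf("event table row %d (event_id=%s): invalid %s: %s",
                 i, if (is.na(df$event_id[i])) "<NA>" else df$event_id[i],
                 field, why), call. = FALSE)
  }
  for (col in c("hpd_old_ma", "hpd_young_ma")) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad)) bad_field(bad[1L], col, "not a finite number")
  }
  neg <- which(df$hpd_young_ma < 0)
  if (length(neg)) bad_field(neg[1L], "hpd_young_ma", "age must be >= 0 Ma")
  inv <- which(df$hpd_young_ma > df$hpd_old_ma)
  if (length(inv)) {
    bad_field(inv[1L], "hpd_young_ma",
              sprintf("younger bound (%g) exceeds older bound (%g)",
                      df$hpd_young_ma[inv[1L]], df$hpd_old_ma[inv[1L]]))
  }
  bad_dir <- which(!(df$direction %in% mde_directions()))
  if (length(bad_dir)) {
    bad_field(bad_dir[1L], "direction",
              sprintf("unknown label '%s'", df$direction[bad_dir[1L]]))
  }
  bad_tax <- which(!(df$taxon_group %in% mde_taxa()))
  if (length(bad_tax)) {
    bad_field(bad_tax[1L], "taxon_group",
              sprintf("unknown label '%s'", df$taxon_group[bad_tax[1L]]))
  }
  dup <- which(duplicated(df$event_id))
  if (length(dup)) bad_field(dup[1L], "event_id", "duplicate identifier")
  invisible(df)
}

#' Read a dispersal-event table from TSV
#'
#' The on-disk dialect is tab-separated UTF-8 with a header row carrying the
#' exact column names `event_id`, `dataset_id`, `taxon_group`, `direction`,
#' `hpd_old_ma`, `hpd_young_ma`. Ages are parsed as decimal Ma; rounding to
#' integer slices happens later, in [compute_mde()], so the raw data stay
#' lossless. Row order is preserved.
#'
#' @param path path to a TSV file.
#' @return An `event_table`.
#' @seealso [write_events()], [filter_events()]
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(.event_cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df <- df[, .event_cols, drop = FALSE]
  for (col in c("hpd_old_ma", "hpd_young_ma")) {
    val <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(val) & nzchar(df[[col]]))
    if (length(bad)) {
      stop(sprintf("%s row %d: cannot parse %s value '%s' as an age in Ma",
                   path, bad[1L], col, df[[col]][bad[1L]]), call. = FALSE)
    }
    df[[col]] <- val
  }
  validate_events(df)
  structure(df, class = c("event_table", "data.frame"),
            metadata = list(source = path))
}

#' Write a dispersal-event table to TSV
#'
#' Ages are written with full double precision so that
#' `read_events(write_events(t))` reproduces `t` field-for-field.
#'
#' @param table an `event_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(table, path) {
  validate_events(table)
  out <- as.data.frame(table)
  out$hpd_old_ma <- sprintf("%.17g", out$hpd_old_ma)
  out$hpd_young_ma <- sprintf("%.17g", out$hpd_young_ma)
  utils::write.table(out[, .event_cols, drop = FALSE], file = path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Filter events by direction and/or taxon group
#'
#' Subsets an event table, preserving row order. With no filters the table is
#' returned unchanged. Filtering by direction yields a two-part partition of
#' the table; filtering by the eight taxon groups partitions it as well, since
#' each event carries exactly one group.
#'
#' @param table an `event_table`.
#' @param direction optional single direction label ([mde_directions()]).
#' @param taxa optional character vector of taxon groups ([mde_taxa()]).
#' @return The filtered `event_table`.
#' @examples
#' tab <- event_table(event_id = c("a", "b"), dataset_id = "d",
#'                    taxon_group = c("bird", "plant"),
#'                    direction = "asia_to_india",
#'                    hpd_old_ma = c(5, 40), hpd_young_ma = c(1, 22))
#' nrow(filter_events(tab, taxa = "bird"))
#' @export
filter_events <- function(table, direction = NULL, taxa = NULL) {
  validate_events(table)
  keep <- rep(TRUE, nrow(table))
  if (!is.null(direction)) {
    if (length(direction) != 1L || !(direction %in% mde_directions())) {
      stop("unknown direction label: ", paste(direction, collapse = ", "),
           call. = FALSE)
    }
    keep <- keep & table$direction == direction
  }
  if (!is.null(taxa)) {
    bad <- setdiff(taxa, mde_taxa())
    if (length(bad)) {
      stop("unknown taxon label(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    keep <- keep & table$taxon_group %in% taxa
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("event_table", "data.frame"),
            metadata = attr(table, "metadata"))
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("Dispersal-event table: %d event(s), %d dataset(s)\n",
              nrow(x), length(unique(x$dataset_id))))
  if (nrow(x)) {
    dirs <- table(factor(x$direction, levels = mde_directions()))
    cat("  directions: ",
        paste(sprintf("%s=%d", names(dirs), dirs), collapse = ", "), "\n",
        sep = "")
    cat(sprintf("  HPD span: %.2f-%.2f Ma\n",
                min(x$hpd_young_ma), max(x$hpd_old_ma)))
  }
  NextMethod()
  invisible(x)
}
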