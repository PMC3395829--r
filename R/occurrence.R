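# Metadata parsing/validation, supercontinent mapping, VT x category
# incidence matrices and the sampling-sufficiency filters.

.META_COLUMNS <- c("seq_id", "host_order", "functional_group", "ecosystem",
                   "continent", "realm", "climate", "location_id", "origin")

#' Controlled vocabularies for sample metadata
#'
#' The categorical schemes used throughout: host functional groups, the five
#' ecosystem types, six continents, eight biogeographical realms, the five
#' Koeppen-Geiger climate classes, and sequence origins.  Host plant orders
#' and location ids are free-form (nonempty) labels.
#'
#' @return Named list of character vectors.
#' @export
metadata_vocabulary <- function() {
  list(
    functional_group = c("forb", "grass", "woody"),
    ecosystem = c("anthropogenic", "forest", "grassland", "shrubland",
                  "successional"),
    continent = c("Africa", "Asia", "Europe", "North America", "Oceania",
                  "South America"),
    realm = c("Afrotropic", "Antarctic", "Australasia", "Indo-Malay",
              "Nearctic", "Neotropic", "Oceania", "Palearctic"),
    climate = c("arid", "equatorial", "polar", "snow", "warm temperate"),
    origin = c("root", "soil", "spore")
  )
}

# Internal: validate a metadata data.frame; collects all violations before
# erroring.
.validate_metadata <- function(df) {
  missing_cols <- setdiff(.META_COLUMNS, names(df))
  if (length(missing_cols))
    stop("missing metadata columns: ", paste(missing_cols, collapse = ", "))
  df <- df[, .META_COLUMNS, drop = FALSE]
  for (j in names(df)) df[[j]] <- as.character(df[[j]])
  if (nrow(df) == 0) return(df)
  if (anyDuplicated(df$seq_id))
    stop("duplicate seq_id in metadata: ",
         paste(unique(df$seq_id[duplicated(df$seq_id)]), collapse = ", "))
  vocab <- metadata_vocabulary()
  bad <- character(0)
  for (col in names(vocab)) {
    off <- which(!df[[col]] %in% vocab[[col]])
    if (length(off))
      bad <- c(bad, sprintf("row %d: %s '%s' not in vocabulary",
                            off, col, df[[col]][off]))
  }
  for (col in c("seq_id", "host_order", "location_id")) {
    off <- which(is.na(df[[col]]) | !nzchar(df[[col]]))
    if (length(off))
      bad <- c(bad, sprintf("row %d: empty %s", off, col))
  }
  if (length(bad))
    stop("metadata validation failed:\n", paste(bad, collapse = "\n"))
  df
}

#' Read and validate per-sequence metadata
#'
#' Reads a tab-separated metadata table with columns \code{seq_id},
#' \code{host_order}, \code{functional_group}, \code{ecosystem},
#' \code{continent}, \code{realm}, \code{climate}, \code{location_id},
#' \code{origin}.  All vocabulary violations are collected and reported
#' together; duplicate sequence ids are an error; a header-only file yields
#' an empty table with a warning.
#'
#' @param path Path to the TSV file (header required).
#' @return A validated data.frame, one row per sequence.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          quote = "", comment.char = "")
  df <- .validate_metadata(df)
  if (nrow(df) == 0) warning("metadata file has a header but no rows")
  message(sprintf("read %d metadata rows", nrow(df)))
  df
}

#' Map continent (and realm) to supercontinent
#'
#' North America, Europe and Asia map to Laurasia; Africa, South America and
#' Oceania map to Gondwana.  Samples from the Indo-Malay realm map to
#' Gondwana regardless of continent, because India rode with the southern
#' landmass.
#'
#' @param continent Character vector of continents.
#' @param realm Optional character vector of biogeographical realms.
#' @return Character vector of "Laurasia"/"Gondwana".
#' @export
map_supercontinent <- function(continent, realm = NULL) {
  vocab <- metadata_vocabulary()
  if (any(!continent %in% vocab$continent))
    stop("invalid continent: ",
         paste(unique(continent[!continent %in% vocab$continent]),
               collapse = ", "))
  laurasia <- c("North America", "Europe", "Asia")
  out <- ifelse(continent %in% laurasia, "Laurasia", "Gondwana")
  if (!is.null(realm)) out[realm == "Indo-Malay"] <- "Gondwana"
  out
}

#' Virtual-taxon incidence matrix over a category scheme
#'
#' Counts, for every VT and every category label, the number of sequences
#' of that VT carrying that label.  \code{scheme} may be any metadata
#' column, \code{"location"} (the location id) or \code{"supercontinent"}
#' (derived from continent and realm).
#'
#' @param assignment A \code{vt_assignment}.
#' @param meta Metadata data.frame (see \code{\link{read_metadata}}).
#' @param scheme Category scheme.
#' @param origin Optional origin filter (e.g. \code{"root"} to restrict to
#'   root-derived sequences for host-linked analyses); NULL keeps all.
#' @return Integer matrix, rows = VT ids, columns = category labels, with
#'   attribute \code{"scheme"}.
#' @export
incidence_matrix <- function(assignment, meta, scheme, origin = NULL) {
  membership <- vt_membership(assignment)
  rownames(meta) <- meta$seq_id
  if (!is.null(origin)) {
    meta <- meta[meta$origin %in% origin, , drop = FALSE]
    membership <- membership[names(membership) %in% meta$seq_id]
  }
  missing <- setdiff(names(membership), meta$seq_id)
  if (length(missing))
    stop("sequences without metadata: ", paste(missing, collapse = ", "))
  meta <- meta[names(membership), , drop = FALSE]
  labels <- switch(scheme,
    location = meta$location_id,
    supercontinent = map_supercontinent(meta$continent, meta$realm),
    {
      if (!scheme %in% names(meta)) stop("unknown scheme: ", scheme)
      meta[[scheme]]
    })
  tab <- table(factor(membership), factor(labels))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  attr(m, "scheme") <- scheme
  m
}

#' Presence/absence view of an incidence matrix
#'
#' @param m Count matrix.
#' @return Logical matrix of the same shape.
#' @export
presence <- function(m) {
  structure(m > 0, dimnames = dimnames(m))
}

#' Cross-tabulate two metadata fields
#'
#' Utility for composition tables that are not VT-based, e.g. host plant
#' order by ecosystem.
#'
#' @param meta Metadata data.frame.
#' @param row_field,col_field Metadata column names (or
#'   \code{"supercontinent"}).
#' @return Integer count matrix.
#' @export
cross_tabulate <- function(meta, row_field, col_field) {
  get <- function(f)
    if (f == "supercontinent") map_supercontinent(meta$continent, meta$realm)
    else if (f == "location") meta$location_id
    else meta[[f]]
  tab <- table(factor(get(row_field)), factor(get(col_field)))
  matrix(as.integer(tab), nrow = nrow(tab), dimnames = dimnames(tab))
}

#' Apply sampling-sufficiency filters to an incidence matrix
#'
#' Columns named \code{Indo-Malay} or \code{shrubland} are always dropped
#' (insufficient sampling in the source corpus design).  In
#' \code{"location"} mode a column is retained when it has at least 12
#' sequences OR at least 6 VTs; in \code{"plant"} mode a column needs at
#' least 3 VTs.  Dropped columns are recorded in the \code{"dropped"}
#' attribute.
#'
#' @param m Count matrix (rows VTs, columns categories/locations/plants).
#' @param mode One of \code{"none"}, \code{"location"}, \code{"plant"}.
#' @return The filtered matrix; errors if every column would be dropped.
#' @export
apply_filters <- function(m, mode = c("none", "location", "plant")) {
  mode <- match.arg(mode)
  drop_always <- colnames(m) %in% c("Indo-Malay", "shrubland")
  n_seq <- colSums(m)
  n_vt <- colSums(m > 0)
  keep <- !drop_always
  if (mode == "location") keep <- keep & (n_seq >= 12 | n_vt >= 6)
  if (mode == "plant") keep <- keep & (n_vt >= 3)
  dropped <- colnames(m)[!keep]
  if (!any(keep)) stop("all columns removed by filtering")
  out <- m[, keep, drop = FALSE]
  attr(out, "scheme") <- attr(m, "scheme")
  attr(out, "dropped") <- dropped
  out
}
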