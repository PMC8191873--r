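# Alignment and metadata input/output, reference coordinate mapping and
# pairwise identity. Coordinates are 1-based and inclusive throughout, in the
# numbering of a designated reference sequence (human beta-myosin numbering
# for the motivating data set). Columns where the numbering reference is
# gapped carry "AliPos-<column>" labels instead of residue numbers.

AMBIGUITY_LETTERS <- c("B", "Z", "X", "J", "U", "O")
GAP <- "-"

#' Construct and validate a gapped protein alignment
#'
#' @param seqs named character vector of aligned sequences (names are species
#'   ids). All sequences must have equal length; letters are uppercased.
#' @param reference_id species id used as the coordinate/identity reference;
#'   must be present among `names(seqs)`.
#' @return an object of class `myo_alignment`: a list with `records` (named
#'   uppercase character vector), `length` (columns) and `reference_id`.
#' @export
new_alignment <- function(seqs, reference_id) {
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
    fail("all sequences must be named by species id")
  if (anyDuplicated(names(seqs)))
    fail("duplicate species id: ", names(seqs)[duplicated(names(seqs))][1L])
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    bad <- names(seqs)[lens != lens[1L]][1L]
    fail("sequences differ in length: record '", bad, "' has ",
         nchar(seqs[[bad]]), " columns, expected ", lens[1L])
  }
  if (!reference_id %in% names(seqs))
    fail("reference_id '", reference_id, "' not present in the alignment")
  letters_used <- unique(strsplit(paste(seqs, collapse = ""), "")[[1L]])
  amb <- intersect(letters_used, AMBIGUITY_LETTERS)
  if (length(amb))
    warning("ambiguity letters present (never counted as matches): ",
            paste(amb, collapse = ", "), call. = FALSE)
  structure(
    list(records = seqs, length = unname(lens[1L]), reference_id = reference_id),
    class = "myo_alignment"
  )
}

#' Read a gapped FASTA alignment
#'
#' @inheritParams new_alignment
#' @param path FASTA file with one record per species, all the same length.
#' @return a `myo_alignment`.
#' @export
read_alignment <- function(path, reference_id) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  # keep only the first whitespace-delimited token of each FASTA header
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1L)
  new_alignment(seqs, reference_id)
}

#' Write an alignment as gapped FASTA
#'
#' @param alignment a `myo_alignment`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(alignment, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(alignment$records), path)
  invisible(path)
}

# alignment as a species x column character matrix
alignment_matrix <- function(alignment) {
  m <- do.call(rbind, strsplit(alignment$records, ""))
  rownames(m) <- names(alignment$records)
  m
}

sniff_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Read a species metadata table
#'
#' Expects a delimited table (comma or tab, sniffed) with columns
#' `species_id`, `mass_kg` and `clade`; `display_name` is optional.
#'
#' @param path metadata file.
#' @param clade_levels optional controlled vocabulary; when given, any clade
#'   label outside it is an error.
#' @return data.frame with one row per species, masses as positive numerics.
#' @export
read_species_metadata <- function(path, clade_levels = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = sniff_sep(path),
                          stringsAsFactors = FALSE, comment.char = "")
  need <- c("species_id", "mass_kg", "clade")
  miss <- setdiff(need, names(df))
  if (length(miss)) fail("metadata lacks column(s): ", paste(miss, collapse = ", "))
  validate_metadata(df, clade_levels)
}

validate_metadata <- function(df, clade_levels = NULL) {
  if (anyDuplicated(df$species_id))
    fail("duplicate species_id: ", df$species_id[duplicated(df$species_id)][1L])
  mass <- suppressWarnings(as.numeric(df$mass_kg))
  if (anyNA(mass) || any(mass <= 0))
    fail("mass_kg must be positive for every species")
  df$mass_kg <- mass
  if (!is.null(clade_levels)) {
    bad <- setdiff(unique(df$clade), clade_levels)
    if (length(bad)) fail("clade label(s) outside vocabulary: ",
                          paste(bad, collapse = ", "))
  }
  df
}

#' Write a species metadata table (TSV)
#' @param metadata data.frame as returned by [read_species_metadata()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_species_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a region table (name, start, end, role)
#' @param path delimited file with headers name, start, end, role.
#' @return data.frame of validated regions.
#' @export
read_regions <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = sniff_sep(path),
                          stringsAsFactors = FALSE)
  if (any(df$start < 1) || any(df$start > df$end))
    fail("regions require 1 <= start <= end")
  df
}

#' Read a residue annotation table (residue, category, substitution)
#' @param path delimited file with headers residue, category and optionally
#'   substitution (e.g. "E44D").
#' @return data.frame of annotations.
#' @export
read_annotations <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = sniff_sep(path),
                          stringsAsFactors = FALSE)
  if (any(df$residue < 1)) fail("annotation residue numbers must be >= 1")
  df
}

#' Map alignment columns to reference residue numbers
#'
#' Columns where the reference carries a residue receive successive residue
#' numbers starting at `offset`; columns where the reference is gapped
#' receive alignment-only labels `AliPos-<column>`.
#'
#' @param alignment a `myo_alignment`.
#' @param offset residue number of the reference's first ungapped column.
#' @return data.frame with `column`, `label` and `ref_number` (NA on AliPos
#'   columns).
#' @export
map_reference_coordinates <- function(alignment, offset = 1L) {
  ref <- strsplit(alignment$records[[alignment$reference_id]], "")[[1L]]
  ungapped <- ref != GAP
  ref_number <- rep(NA_integer_, alignment$length)
  ref_number[ungapped] <- seq.int(offset, length.out = sum(ungapped))
  label <- ifelse(ungapped, as.character(ref_number),
                  paste0("AliPos-", seq_len(alignment$length)))
  data.frame(column = seq_len(alignment$length), label = label,
             ref_number = ref_number, stringsAsFactors = FALSE)
}

#' Extract the columns of a region in reference coordinates
#'
#' Keeps every column whose reference residue number lies in
#' `[start, end]`, plus (by default) AliPos columns interleaved between them.
#'
#' @param alignment a `myo_alignment`.
#' @param columnmap output of [map_reference_coordinates()].
#' @param start,end inclusive reference residue bounds.
#' @param include_alipos keep reference-gap columns lying inside the region?
#' @param clip clip out-of-range endpoints to the mapped range instead of
#'   erroring?
#' @return a `myo_alignment` over the selected columns.
#' @export
slice_region <- function(alignment, columnmap, start, end,
                         include_alipos = TRUE, clip = FALSE) {
  if (start > end) fail("region start (", start, ") exceeds end (", end, ")")
  nums <- columnmap$ref_number
  if (clip) {
    start <- max(start, min(nums, na.rm = TRUE))
    end <- min(end, max(nums, na.rm = TRUE))
  }
  numbered <- which(!is.na(nums) & nums >= start & nums <= end)
  if (!length(numbered)) fail("region [", start, ", ", end,
                              "] selects no reference columns")
  keep <- if (include_alipos) seq.int(min(numbered), max(numbered)) else numbered
  records <- vapply(alignment$records, function(s)
    paste(strsplit(s, "")[[1L]][keep], collapse = ""), "")
  suppressWarnings(new_alignment(records, alignment$reference_id))
}

#' Percent identity between two aligned sequences
#'
#' @param alignment a `myo_alignment`.
#' @param species_a,species_b species ids present in the alignment.
#' @param denominator `"ungapped_pair"` (default): columns where both
#'   sequences carry a residue; `"alignment_length"`: all columns (gap vs
#'   residue and gap vs gap count as mismatch and match is still letter
#'   equality on residues only).
#' @return percent identity in \[0, 100\]. Ambiguity letters never count as
#'   matches. Self-comparison returns 100.
#' @export
pairwise_identity <- function(alignment, species_a, species_b,
                              denominator = c("ungapped_pair", "alignment_length")) {
  denominator <- match.arg(denominator)
  for (sp in c(species_a, species_b))
    if (!sp %in% names(alignment$records))
      fail("species '", sp, "' not in the alignment")
  if (species_a == species_b) return(100)
  a <- strsplit(alignment$records[[species_a]], "")[[1L]]
  b <- strsplit(alignment$records[[species_b]], "")[[1L]]
  both <- a != GAP & b != GAP
  match_ok <- both & a == b & !(a %in% AMBIGUITY_LETTERS)
  denom <- if (denominator == "ungapped_pair") sum(both) else length(a)
  if (denom == 0) fail("no comparable (mutually ungapped) columns between '",
                       species_a, "' and '", species_b, "'")
  100 * sum(match_ok) / denom
}

#' Identity of every species to the identity reference, joined with masses
#'
#' @param alignment a `myo_alignment`.
#' @param metadata data.frame from [read_species_metadata()]; must cover all
#'   alignment species.
#' @param reference_id identity reference (defaults to the alignment's
#'   reference). The reference row is included with identity 100; fitting
#'   excludes it by default downstream.
#' @inheritParams pairwise_identity
#' @return data.frame `species_id`, `identity_pct`, `mass_kg`, `clade`.
#' @export
identity_series <- function(alignment, metadata,
                            reference_id = alignment$reference_id,
                            denominator = "ungapped_pair") {
  sp <- names(alignment$records)
  miss <- setdiff(sp, metadata$species_id)
  if (length(miss)) fail("metadata lacks species: ", paste(miss, collapse = ", "))
  idx <- match(sp, metadata$species_id)
  data.frame(
    species_id = sp,
    identity_pct = vapply(sp, function(s)
      pairwise_identity(alignment, reference_id, s, denominator), 0),
    mass_kg = metadata$mass_kg[idx],
    clade = metadata$clade[idx],
    row.names = NULL, stringsAsFactors = FALSE
  )
}
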