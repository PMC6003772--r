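#' Read a FASTQ file into a tibble
#'
#' Four-line FASTQ records; sequences are normalised to the RNA alphabet
#' (`T`/`t` become `U`, everything uppercased). Malformed files raise an error
#' naming the first offending record.
#'
#' @param path Path to an uncompressed FASTQ file.
#' @return Tibble with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  check_fastq_structure(path)
  x <- Biostrings::readBStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble(
    id = names(x),
    seq = unname(chartr("Tt", "Uu", toupper(as.character(x)))),
    qual = unname(as.character(S4Vectors::mcols(x)$qualities))
  )
}

# Structural validation giving record-indexed errors.
check_fastq_structure <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4L != 0L)
    abort(sprintf("truncated FASTQ: record %d is incomplete in '%s'.",
                  length(lines) %/% 4L + 1L, path))
  heads <- lines[seq(1L, length(lines), by = 4L)]
  plus <- lines[seq(3L, length(lines), by = 4L)]
  bad <- which(!startsWith(heads, "@") | !startsWith(plus, "+"))
  if (length(bad))
    abort(sprintf("malformed FASTQ record %d in '%s'.", bad[1L], path))
  invisible(TRUE)
}

#' Write reads to a FASTQ file
#'
#' @param reads Tibble with columns `id`, `seq` and optionally `qual`
#'   (constant `I` qualities are written when absent).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq") %in% names(reads)))
  qual <- if ("qual" %in% names(reads)) reads$qual else strrep("I", nchar(reads$seq))
  writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", qual), path)
  invisible(path)
}

#' Read a FASTA file into a tibble
#'
#' Sequences are normalised to the RNA alphabet.
#'
#' @param path Path to an uncompressed FASTA file.
#' @return Tibble with columns `id`, `seq`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path, format = "fasta")
  tibble(id = names(x), seq = chartr("Tt", "Uu", toupper(as.character(x))))
}

#' Serialise an assay design to YAML
#'
#' @param design An [assay_design()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assay_design <- function(design, path) {
  validate_assay_design(design)
  yaml::write_yaml(
    list(
      primer_core = attr(design, "primer_core"),
      adaptor = attr(design, "adaptor"),
      templates = purrr::pmap(
        design[c("template_id", "template", "primer_variant")], list
      )
    ),
    path
  )
  invisible(path)
}

#' Read an assay design from YAML
#'
#' @param path Path written by [write_assay_design()].
#' @return An [assay_design()].
#' @export
read_assay_design <- function(path) {
  y <- yaml::read_yaml(path)
  assay_design(dplyr::bind_rows(y$templates),
               primer_core = y$primer_core, adaptor = y$adaptor)
}

#' Read/write TSV ladders and dose-response tables
#'
#' Plain TSV with a header: ladders have columns `n_added`, `intensity`;
#' dose-response tables have columns `conc`, `response`.
#'
#' @param path File path.
#' @return `read_ladder()` returns a `ladder` tibble; `read_dose_response()`
#'   a tibble with columns `conc`, `response`.
#' @name tsv_io
#' @export
read_ladder <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    n_added = readr::col_integer(), intensity = readr::col_double()
  ))
  structure(as_tibble(x), class = c("ladder", class(tibble())))
}

#' @rdname tsv_io
#' @param ladder A `ladder` tibble.
#' @export
write_ladder <- function(ladder, path) {
  readr::write_tsv(as_tibble(ladder), path)
  invisible(path)
}

#' @rdname tsv_io
#' @export
read_dose_response <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    conc = readr::col_double(), response = readr::col_double()
  ))
}

#' @rdname tsv_io
#' @param dose A dose-response tibble (`conc`, `response`).
#' @export
write_dose_response <- function(dose, path) {
  readr::write_tsv(dose, path)
  invisible(path)
}

#' Read/write triplet count tables as TSV
#'
#' Columns: `template_id`, `triplet`, `count`, `sample_kind`. Discard tallies
#' are carried in a sidecar-style attribute and serialised alongside as JSON
#' when `sidecar = TRUE`.
#'
#' @param counts A `triplet_counts` table.
#' @param path Output TSV path.
#' @param sidecar Also write `<path>.json` with discard tallies and metadata.
#' @return `path`, invisibly.
#' @export
write_triplet_counts <- function(counts, path, sidecar = TRUE) {
  readr::write_tsv(as_tibble(counts), path)
  if (sidecar) {
    jsonlite::write_json(
      list(
        sample_kind = attr(counts, "sample_kind"),
        n_reads = attr(counts, "n_reads"),
        discards = attr(counts, "discards")
      ),
      paste0(path, ".json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}

#' @rdname write_triplet_counts
#' @export
read_triplet_counts <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    template_id = readr::col_character(), triplet = readr::col_character(),
    count = readr::col_double(), sample_kind = readr::col_character()
  ))
  out <- as_tibble(x)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    attr(out, "sample_kind") <- meta$sample_kind
    attr(out, "n_reads") <- meta$n_reads
    attr(out, "discards") <- if (length(meta$discards)) {
      as_tibble(meta$discards)
    } else {
      tibble(reason = character(), n = integer())
    }
  } else {
    attr(out, "sample_kind") <- unique(x$sample_kind)
  }
  class(out) <- c("triplet_counts", class(tibble()))
  out
}
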