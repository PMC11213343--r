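AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

check_aa <- function(seq, what) {
  bad <- setdiff(strsplit(seq, "")[[1L]], AA_LETTERS)
  if (length(bad) > 0L) {
    stop(what, " contains non-amino-acid characters: ",
         paste(unique(bad), collapse = ""), call. = FALSE)
  }
}

#' Assemble one effector-insertion sensor sequence
#'
#' Places the effector cassette between scaffold positions `i` and `i + 1`
#' with the duplicated-residue linkers used for circularly permuted GFP
#' insertions: the N-terminal linker is res(i+1)-Ala-Ser and the C-terminal
#' linker is Ala-Ser-res(i), so
#'
#' `full = scaffold[1..i] + scaffold[i+1] + AS + effector + AS + scaffold[i] + scaffold[i+1..n]`
#'
#' and residues i and i+1 each appear twice. The full length is always
#' scaffold + effector + 6.
#'
#' @param scaffold_seq Scaffold amino-acid sequence (one-letter).
#' @param i Insertion site, `1 <= i <= nchar(scaffold_seq) - 1`.
#' @param effector_seq Effector amino-acid sequence.
#' @param scaffold_id,effector_id Names used for the construct label
#'   `scaffoldID_i-effectorID`.
#' @return One-row tibble: `name`, `site`, `scaffold_len`, `effector_len`,
#'   `full_len`, `full_seq`.
#' @export
build_sensor_sequence <- function(scaffold_seq, i, effector_seq,
                                  scaffold_id = "MBP",
                                  effector_id = "cpGFP") {
  check_aa(scaffold_seq, "scaffold")
  check_aa(effector_seq, "effector")
  n <- nchar(scaffold_seq)
  if (n < 2L) stop("scaffold must have at least 2 residues", call. = FALSE)
  if (i < 1L || i > n - 1L) {
    stop("insertion site ", i, " out of range 1..", n - 1L, call. = FALSE)
  }
  res_i <- substr(scaffold_seq, i, i)
  res_i1 <- substr(scaffold_seq, i + 1L, i + 1L)
  full <- paste0(
    substr(scaffold_seq, 1L, i),
    res_i1, "AS", effector_seq, "AS", res_i,
    substr(scaffold_seq, i + 1L, n)
  )
  tibble::tibble(
    name = paste0(scaffold_id, "_", i, "-", effector_id),
    site = as.integer(i),
    scaffold_len = n,
    effector_len = nchar(effector_seq),
    full_len = nchar(full),
    full_seq = full
  )
}

#' Design a batch of sensor constructs
#'
#' One construct per insertion site (duplicates are collapsed with a
#' warning), named `scaffoldID_i-effectorID` in site order.
#'
#' @inheritParams build_sensor_sequence
#' @param sites Integer vector of insertion sites.
#' @return Tibble of constructs (rows as in [build_sensor_sequence()]).
#' @export
batch_design <- function(scaffold_seq, effector_seq, sites,
                         scaffold_id = "MBP", effector_id = "cpGFP") {
  sites <- as.integer(sites)
  if (anyDuplicated(sites)) {
    warning("duplicate insertion sites collapsed: ",
            paste(unique(sites[duplicated(sites)]), collapse = ", "),
            call. = FALSE)
    sites <- unique(sites)
  }
  purrr::map_dfr(sites, function(s) {
    build_sensor_sequence(scaffold_seq, s, effector_seq,
                          scaffold_id = scaffold_id,
                          effector_id = effector_id)
  })
}

#' Read the first sequence of a FASTA file
#'
#' @param path FASTA path.
#' @return Named character scalar (name = FASTA record id).
#' @export
read_fasta_seq <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("no sequences in '", path, "'", call. = FALSE)
  seq <- as.character(set[[1L]])
  names(seq) <- sub("\\s.*$", "", names(set)[1L])
  seq
}

#' Write designed constructs to a FASTA file
#'
#' @param designs Tibble from [batch_design()].
#' @param path Output path.
#' @export
write_constructs_fasta <- function(designs, path) {
  set <- Biostrings::AAStringSet(designs$full_seq)
  names(set) <- designs$name
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
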