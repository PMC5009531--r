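# Three-letter <-> one-letter residue code maps (standard 20).
.aa3to1 <- c(
  ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F",
  GLY = "G", HIS = "H", ILE = "I", LYS = "K", LEU = "L",
  MET = "M", ASN = "N", PRO = "P", GLN = "Q", ARG = "R",
  SER = "S", THR = "T", VAL = "V", TRP = "W", TYR = "Y"
)
.aa1to3 <- setNames(names(.aa3to1), unname(.aa3to1))

#' Read per-residue Calpha B-factors from a PDB file
#'
#' Parses fixed-column `ATOM` records and extracts, for every residue of
#' every chain, the temperature factor (columns 61-66) of its CA atom.
#' Residues that have atoms but no CA atom get a missing `raw_bfactor`.
#' `HETATM` records (modified or non-standard residues) are ignored;
#' non-standard residue names on `ATOM` records are read as `"X"`.
#' Alternate locations of the same CA atom are resolved by highest
#' occupancy, ties going to the record that appears first in the file.
#'
#' @param path Path to a PDB-format file.
#' @param model Integer; which `MODEL` block to read when the file holds
#'   several (default the first). Files without `MODEL` records are treated
#'   as a single model.
#' @return A tibble with one row per residue: `chain_id`, `position`
#'   (the author residue number), `aa` (one-letter code, `"X"` for
#'   non-standard), `raw_bfactor` (Angstrom^2, `NA` if the residue lacks a
#'   CA atom). Zero rows for a file without ATOM records.
#' @seealso [write_pdb_ca()] for the CA-only writer used by the synthetic
#'   corpus generator.
#' @export
read_pdb_ca_bfactors <- function(path, model = 1L) {
  stopifnot(length(path) == 1L, is.character(path))
  if (!file.exists(path)) abort(paste0("PDB file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) return(.empty_chain_tbl())

  rec <- substr(lines, 1, 6)
  # model bookkeeping: residues before any MODEL record belong to model 1
  model_idx <- cumsum(rec == "MODEL ")
  model_idx[model_idx == 0L] <- 1L
  is_atom <- rec == "ATOM  "
  keep <- which(is_atom & model_idx == as.integer(model))
  if (length(keep) == 0L) return(.empty_chain_tbl())

  ln <- lines[keep]
  bad <- which(nchar(ln) < 66)
  if (length(bad) > 0L) {
    abort(sprintf("malformed ATOM record (shorter than 66 columns) at line %d",
                  keep[bad[1]]))
  }
  resseq <- suppressWarnings(as.integer(substr(ln, 23, 26)))
  occ    <- suppressWarnings(as.numeric(substr(ln, 55, 60)))
  bfac   <- suppressWarnings(as.numeric(substr(ln, 61, 66)))
  bad <- which(is.na(resseq) | is.na(occ) | is.na(bfac))
  if (length(bad) > 0L) {
    abort(sprintf("malformed ATOM record (non-numeric fixed column) at line %d",
                  keep[bad[1]]))
  }

  atoms <- tibble(
    line     = keep,
    atom     = trimws(substr(ln, 13, 16)),
    res3     = trimws(substr(ln, 18, 20)),
    chain_id = substr(ln, 22, 22),
    position = resseq,
    occupancy = occ,
    bfactor  = bfac
  )

  residues <- atoms |>
    dplyr::group_by(.data$chain_id, .data$position) |>
    dplyr::summarise(
      aa = {
        one <- .aa3to1[.data$res3[1]]
        if (is.na(one)) "X" else unname(one)
      },
      raw_bfactor = {
        ca <- which(.data$atom == "CA")
        if (length(ca) == 0L) NA_real_ else {
          best <- ca[order(-.data$occupancy[ca], .data$line[ca])][1]
          .data$bfactor[best]
        }
      },
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$chain_id, .data$position)
  residues
}

.empty_chain_tbl <- function() {
  tibble(chain_id = character(), position = integer(),
         aa = character(), raw_bfactor = double())
}

#' Write CA-only PDB files for a set of chains
#'
#' Emits one fixed-column `ATOM` record per residue (CA atom only), carrying
#' the raw B-factor in columns 61-66 with two decimals. Coordinates are a
#' schematic helical trace; only residue identity and the B column are
#' meaningful. One file per chain is written as `<chain_id>.pdb`.
#'
#' @param chains Tibble with columns `chain_id`, `position`, `aa`,
#'   `raw_bfactor`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_pdb_ca <- function(chains, dir) {
  .check_cols(chains, c("chain_id", "position", "aa", "raw_bfactor"),
              "chains")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- chains |>
    dplyr::group_by(.data$chain_id) |>
    dplyr::group_map(function(df, key) {
      id <- key$chain_id[[1]]
      n <- nrow(df)
      i <- seq_len(n)
      res3 <- .aa1to3[df$aa]
      res3[is.na(res3)] <- "UNK"
      recs <- paste0(
        "ATOM  ", formatC(i, width = 5), "  CA  ",
        formatC(res3, width = 3), " ", substr(id, nchar(id), nchar(id)),
        formatC(df$position, width = 4), "    ",
        sprintf("%8.3f%8.3f%8.3f%6.2f%6.2f",
                2.3 * cos(i * 100 * pi / 180),
                2.3 * sin(i * 100 * pi / 180),
                1.5 * i, 1.00, df$raw_bfactor)
      )
      p <- file.path(dir, paste0(id, ".pdb"))
      writeLines(c(recs, "END"), p)
      p
    }) |>
    unlist()
  invisible(paths)
}

#' Read a directory of single-chain PDB files
#'
#' Reads every `*.pdb` file under `dir` with [read_pdb_ca_bfactors()] and
#' takes the chain identifier from the file name (the PDB chain column holds
#' a single character, too narrow for corpus-scale identifiers).
#'
#' @param dir Directory containing `<chain_id>.pdb` files.
#' @return A residue tibble as from [read_pdb_ca_bfactors()], all files
#'   combined.
#' @export
read_pdb_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.pdb$", full.names = TRUE))
  purrr::map(files, function(p) {
    df <- read_pdb_ca_bfactors(p)
    if (nrow(df) > 0L) df$chain_id <- sub("\\.pdb$", "", basename(p))
    df
  }) |>
    dplyr::bind_rows()
}

# shared column check
.check_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(paste0(what, " is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  invisible(df)
}
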