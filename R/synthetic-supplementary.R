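#' Synthetic stand-in for the four-herb formula's compound table
#'
#' The published study screened 476 chemicals (herb rows 18 + 143 + 48 +
#' 280 = 489, so 13 chemicals are shared between herbs) down to 138
#' candidates, with per-herb candidate contributions 4 + 36 + 14 + 90 = 144
#' (6 candidates shared). Its supplementary table is not deposited with the
#' text, so this constructor builds a synthetic table with exactly those
#' marginal counts: every candidate is given OB/DL values strictly inside
#' the passing region (OB > 30, DL > 0.18) and every other chemical fails
#' at least one threshold. It exercises the screening/deduplication code
#' path at the published scale; the chemical identities are fabricated.
#'
#' @param seed seed for the fabricated OB/DL values.
#' @return Long-format compound data frame (`compound_id,name,herb,ob,dl`,
#'   one row per compound-herb pair; 489 rows over 476 distinct compounds).
#' @export
synthetic_gqd_compound_table <- function(seed = 2019L) {
  set.seed(as.integer(seed))
  herbs <- c(RP = "Radix_Puerariae", SR = "Scutellariae_Radix",
             CR = "Coptidis_Rhizoma", LQ = "Liquorice")

  # candidates: 138 distinct; 6 shared between Scutellariae and liquorice,
  # singles RP 4, SR 30, CR 14, LQ 84 -> herb contributions 4/36/14/90
  cand_assign <- c(rep(list(c("SR", "LQ")), 6),
                   rep(list("RP"), 4), rep(list("SR"), 30),
                   rep(list("CR"), 14), rep(list("LQ"), 84))
  # non-candidates: 338 distinct; 7 shared (SR+LQ);
  # singles RP 14, SR 100, CR 34, LQ 183 -> herb rows 14/107/34/190
  rest_assign <- c(rep(list(c("SR", "LQ")), 7),
                   rep(list("RP"), 14), rep(list("SR"), 100),
                   rep(list("CR"), 34), rep(list("LQ"), 183))

  build <- function(assign, offset, pass) {
    rows <- lapply(seq_along(assign), function(i) {
      id <- sprintf("SYN%04d", offset + i)
      if (pass) {
        ob <- runif(1, 31, 95); dl <- runif(1, 0.19, 0.9)
      } else if (runif(1) < 0.5) {
        ob <- runif(1, 2, 29.5); dl <- runif(1, 0.02, 0.9)
      } else {
        ob <- runif(1, 31, 95); dl <- runif(1, 0.02, 0.17)
      }
      data.frame(compound_id = id, name = paste0("synthetic_", id),
                 herb = herbs[assign[[i]]], ob = ob, dl = dl,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  out <- rbind(build(cand_assign, 0L, TRUE), build(rest_assign, 138L, FALSE))
  rownames(out) <- NULL
  out
}

#' Synthetic stand-in for the disease-target source lists
#'
#' The study merged colorectal-cancer targets from three databases — 47
#' (OMIM), 111 (GAD) and 7 (TTD) — into 150 non-redundant targets, implying
#' 15 redundant memberships. The real lists are not deposited, so this
#' builds three synthetic lists with those sizes and an overlap structure
#' (13 shared OMIM/GAD, 2 shared GAD/TTD, no triple) whose union
#' deduplicates to exactly 150 ids.
#'
#' @return Named list of character vectors `omim` (47), `gad` (111),
#'   `ttd` (7).
#' @export
synthetic_crc_target_lists <- function() {
  ids <- sprintf("TGT%03d", 1:150)
  omim <- ids[1:47]                      # 13 shared with gad: ids 35..47
  gad <- c(ids[35:47], ids[48:143], ids[144:145])  # 13 + 96 + 2 = 111
  ttd <- c(ids[144:145], ids[146:150])   # 2 shared with gad + 5 unique = 7
  list(omim = omim, gad = gad, ttd = ttd)
}
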