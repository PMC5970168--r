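# Published cotton MAPK-cascade data shipped as versioned fixtures:
# the 18 MAPKKK-MKK Y2H interaction pairs, the 16 MKK-MAPK pairs from
# the companion interactome studies, per-treatment induced-gene lists
# from the qRT-PCR survey, the low-expression exclusion set, and the
# MAPK-tier stress-response profiles.

fixture_path <- function(file, dir = NULL) {
  p <- if (is.null(dir))
    system.file("extdata", file, package = "mapkCascades", mustWork = FALSE)
  else file.path(dir, file)
  if (!nzchar(p) || !file.exists(p)) stop("fixture file '", file, "' not found")
  p
}

#' Load the cotton MAPK-cascade fixtures
#'
#' Reads the packaged interaction edge lists, per-treatment induced-gene
#' lists, exclusion set and MAPK-tier response profiles, verifying each
#' file's MD5 checksum against the shipped manifest.
#'
#' Caveats carried in the `flag` column of `induced`: the ABA list is
#' flagged `ambiguous` (the source text states ten induced genes but
#' names only nine distinct ones), and the SA list is flagged
#' `reconstructed` (gene identities assembled from summary statements
#' rather than a printed list).
#'
#' @param verify Verify fixture checksums (default TRUE); a mismatch
#'   signals corrupted data.
#' @param dir Directory holding the fixture files (default: the
#'   installed package's `extdata`).
#' @return List: `edges` (validated [interaction_edges()], both tiers),
#'   `kkk_kk` and `kk_k` subsets, `induced` (data frame: treatment,
#'   gene, peak_time_h, flag), `induced_lists` (per-treatment gene
#'   vectors), `exclusions` (gene, reason), `mapk_profiles` (gene,
#'   treatment, provenance).
#' @export
#' @examples
#' fx <- load_cotton_fixtures()
#' nrow(fx$kkk_kk)  # 18
load_cotton_fixtures <- function(verify = TRUE, dir = NULL) {
  files <- c("cotton_y2h_edges.tsv", "cotton_induced_genes.tsv",
             "cotton_exclusions.tsv", "cotton_mapk_profiles.tsv")
  if (verify) {
    manifest <- jsonlite::read_json(fixture_path("MANIFEST.json", dir),
                                    simplifyVector = TRUE)
    for (f in files) {
      got <- unname(tools::md5sum(fixture_path(f, dir)))
      if (!identical(got, manifest[[f]]))
        stop("fixture checksum mismatch for '", f, "': data corrupted")
    }
  }
  edges <- interaction_edges(read.delim(fixture_path(files[1L], dir),
                                        stringsAsFactors = FALSE))
  induced <- read.delim(fixture_path(files[2L], dir),
                        stringsAsFactors = FALSE)
  exclusions <- read.delim(fixture_path(files[3L], dir),
                           stringsAsFactors = FALSE)
  mapk_profiles <- read.delim(fixture_path(files[4L], dir),
                              stringsAsFactors = FALSE)
  list(edges = edges,
       kkk_kk = edges[edges$tier == "KKK-KK", ],
       kk_k = edges[edges$tier == "KK-K", ],
       induced = induced,
       induced_lists = split(induced$gene, induced$treatment),
       exclusions = exclusions,
       mapk_profiles = mapk_profiles)
}

#' Combined stress-response profiles for cascade annotation
#'
#' Builds the long-format gene x induced-treatment table used by
#' [annotate_shared_responses()]: MAPKKK-tier profiles derived from the
#' per-treatment induced-gene lists (provenance `results_text`) plus the
#' MAPK-tier fixture profiles (provenance `fixture`). MKK-tier profiles
#' are not available and those members are skipped during annotation.
#'
#' @param fixtures Result of [load_cotton_fixtures()] (loaded if NULL).
#' @return Data frame: `gene`, `treatment`, `provenance`.
#' @export
cotton_response_profiles <- function(fixtures = NULL) {
  fx <- fixtures %||% load_cotton_fixtures()
  kkk <- data.frame(gene = fx$induced$gene,
                    treatment = fx$induced$treatment,
                    provenance = "results_text",
                    stringsAsFactors = FALSE)
  rbind(kkk, fx$mapk_profiles)
}
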