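#' Read a species-by-IUCN-category table
#'
#' Expects a delimited text file (tab or comma separated, sniffed from the
#' header line) with columns `order`, `family`, `species`, `common_name`
#' and `iucn` (a `category` column is accepted as a synonym). Category
#' tokens are normalized to upper case; the recognized set is EN, VU, NT,
#' LC, DD and NE (no IUCN record, also accepted as an empty cell).
#'
#' @param path Path to the table.
#' @return A data.frame with columns `order`, `family`, `species`,
#'   `common_name`, `category`, one row per species.
#' @export
read_risk_table <- function(path) {
  stopifnot(file.exists(path))
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0L || !nzchar(trimws(header))) {
    stop("risk table is empty: ", path, call. = FALSE)
  }
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, strip.white = TRUE,
                          fileEncoding = "UTF-8", comment.char = "")
  if (nrow(df) == 0L) stop("risk table has a header but no data rows", call. = FALSE)
  names(df) <- tolower(names(df))
  if ("category" %in% names(df) && !("iucn" %in% names(df))) {
    names(df)[names(df) == "category"] <- "iucn"
  }
  need <- c("species", "iucn")
  if (!all(need %in% names(df))) {
    stop("missing required columns: ", paste(setdiff(need, names(df)), collapse = ", "),
         call. = FALSE)
  }
  for (opt in c("order", "family", "common_name")) {
    if (!opt %in% names(df)) df[[opt]] <- NA_character_
  }
  species <- trimws(df$species)
  if (any(!nzchar(species))) stop("empty species name in row(s) ",
                                  paste(which(!nzchar(species)), collapse = ", "),
                                  call. = FALSE)
  if (anyDuplicated(species)) {
    stop("duplicate species: ",
         paste(unique(species[duplicated(species)]), collapse = ", "), call. = FALSE)
  }
  cat_raw <- toupper(trimws(df$iucn))
  cat_raw[!nzchar(cat_raw)] <- "NE"
  known <- c("EN", "VU", "NT", "LC", "DD", "NE")
  bad <- which(!cat_raw %in% known)
  if (length(bad) > 0L) {
    stop("unknown IUCN category '", df$iucn[bad[1L]], "' in row ", bad[1L], call. = FALSE)
  }
  data.frame(order = df$order, family = df$family, species = species,
             common_name = df$common_name, category = cat_raw,
             stringsAsFactors = FALSE)
}

#' Code IUCN categories to integer risk states
#'
#' Threatened status is placed on the ordinal scale EN = 1, VU = 2, NT = 3,
#' LC = 4 (lower = more threatened). Data-deficient (DD) species and species
#' with no Red List record (NE) carry no usable state and are excluded, with
#' the reason logged.
#'
#' @param records Data frame as returned by [read_risk_table()] (only
#'   `species` and `category` columns are required).
#' @return A `coded_states` object: list with `states` (named integer
#'   vector, values in 1..4) and `exclusions` (data.frame `species`,
#'   `reason`).
#' @export
code_categories <- function(records) {
  stopifnot(is.data.frame(records), all(c("species", "category") %in% names(records)))
  map <- c(EN = 1L, VU = 2L, NT = 3L, LC = 4L)
  cat <- toupper(records$category)
  coded <- cat %in% names(map)
  states <- map[cat[coded]]
  names(states) <- records$species[coded]
  states <- states[order(names(states))]
  excl <- data.frame(
    species = records$species[!coded],
    reason = ifelse(cat[!coded] == "DD", "DD", "no-record"),
    stringsAsFactors = FALSE
  )
  excl <- excl[order(excl$species), , drop = FALSE]
  rownames(excl) <- NULL
  structure(list(states = states, exclusions = excl), class = "coded_states")
}

#' @export
print.coded_states <- function(x, ...) {
  tab <- table(factor(x$states, levels = 1:4, labels = c("EN", "VU", "NT", "LC")))
  cat("coded_states:", length(x$states), "species coded (",
      paste(names(tab), tab, collapse = ", "), "),",
      nrow(x$exclusions), "excluded\n")
  invisible(x)
}

#' Restrict coded states to the tips of a tree
#'
#' Species names are matched after normalizing spaces vs underscores and
#' case; no fuzzy matching is attempted. Species absent from the tree are
#' moved to the exclusion log with reason `not-in-tree`; tips without a
#' state are reported via a warning (they must be resolved before a
#' likelihood can be computed).
#'
#' @param states A `coded_states` object.
#' @param tree A `phylo` whose tip labels are the species binomials.
#' @return A `coded_states` object whose states are named by the tree's tip
#'   labels (tree orthography wins); errors if fewer than 3 species match.
#' @export
match_to_tree <- function(states, tree) {
  stopifnot(inherits(states, "coded_states"))
  validate_phylogeny(tree)
  norm <- function(x) tolower(gsub("[ _]+", "_", trimws(x)))
  tip_n <- norm(tree$tip.label)
  st_n <- norm(names(states$states))
  hit <- match(st_n, tip_n)
  matched <- !is.na(hit)
  if (sum(matched) < 3L) {
    stop("only ", sum(matched), " species match the tree tips; ",
         "need at least 3 for a comparative analysis", call. = FALSE)
  }
  out <- states$states[matched]
  names(out) <- tree$tip.label[hit[matched]]
  out <- out[order(match(names(out), tree$tip.label))]
  excl <- states$exclusions
  if (any(!matched)) {
    excl <- rbind(excl, data.frame(species = names(states$states)[!matched],
                                   reason = "not-in-tree", stringsAsFactors = FALSE))
  }
  unstated <- setdiff(tip_n, st_n)
  if (length(unstated) > 0L) {
    warning(length(unstated), " tree tip(s) have no coded state: ",
            paste(tree$tip.label[match(unstated, tip_n)], collapse = ", "))
  }
  structure(list(states = out, exclusions = excl), class = "coded_states")
}

# Accept either a coded_states object or a bare named vector of states.
.state_vector <- function(states) {
  if (inherits(states, "coded_states")) states <- states$states
  if (is.null(names(states)) || any(!nzchar(names(states)))) {
    stop("states must be named by species/tip label", call. = FALSE)
  }
  states
}
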