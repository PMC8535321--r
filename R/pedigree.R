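#' Construct a pedigree
#'
#' A pedigree is the inheritance scaffold for everything else in the package:
#' linkage, kinship, gene dropping and family-based burden testing all consume
#' it. Founders have both parents absent; every non-founder has exactly two
#' parents that resolve within the pedigree.
#'
#' @param id character vector of individual identifiers (unique).
#' @param father,mother parent identifiers; `NA` (or `"0"`) for founders.
#' @param sex `"male"`, `"female"` or `"unknown"`.
#' @param affected `"yes"`, `"no"` or `"unknown"`.
#' @param genotyped logical; whether the individual has genotype data.
#' @param family optional single family identifier (used when writing PED).
#'
#' @return An object of class `pedigree`: a data frame with columns
#'   `id`, `father`, `mother`, `sex`, `affected`, `genotyped`, plus a
#'   `topo` attribute giving a parent-before-child ordering.
#' @export
pedigree <- function(id, father = NA, mother = NA,
                     sex = "unknown", affected = "unknown",
                     genotyped = TRUE, family = "FAM1") {
  n <- length(id)
  id <- as.character(id)
  norm_parent <- function(p) {
    p <- as.character(rep_len(p, n))
    p[!is.na(p) & p %in% c("0", "")] <- NA_character_
    p
  }
  father <- norm_parent(father)
  mother <- norm_parent(mother)
  sex <- match.arg(rep_len(as.character(sex), n),
                   c("male", "female", "unknown"), several.ok = TRUE)
  affected <- match.arg(rep_len(as.character(affected), n),
                        c("yes", "no", "unknown"), several.ok = TRUE)
  genotyped <- rep_len(as.logical(genotyped), n)

  if (anyDuplicated(id))
    stop("duplicated individual ids: ", paste(unique(id[duplicated(id)]), collapse = ", "))
  one_parent <- xor(is.na(father), is.na(mother))
  if (any(one_parent))
    stop("individuals with exactly one parent (must be 0 or 2): ",
         paste(id[one_parent], collapse = ", "))
  bad_ref <- c(setdiff(stats::na.omit(father), id), setdiff(stats::na.omit(mother), id))
  if (length(bad_ref))
    stop("unresolved parent id(s): ", paste(unique(bad_ref), collapse = ", "))
  for (i in seq_len(n)) {
    if (!is.na(father[i]) && sex[match(father[i], id)] == "female")
      stop("father ", father[i], " is recorded as female")
    if (!is.na(mother[i]) && sex[match(mother[i], id)] == "male")
      stop("mother ", mother[i], " is recorded as male")
  }

  ped <- data.frame(id = id, father = father, mother = mother,
                    sex = sex, affected = affected, genotyped = genotyped,
                    stringsAsFactors = FALSE)
  attr(ped, "family") <- as.character(family)[1]
  attr(ped, "topo") <- ped_topo_order(ped)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# Kahn topological sort; detects parentage cycles (an individual that is its
# own ancestor, including self-parenting).
ped_topo_order <- function(ped) {
  n <- nrow(ped)
  fa <- match(ped$father, ped$id)
  mo <- match(ped$mother, ped$id)
  indeg <- (!is.na(fa)) + (!is.na(mo))
  order <- integer(0)
  ready <- which(indeg == 0L)
  placed <- rep(FALSE, n)
  while (length(ready)) {
    i <- ready[1]; ready <- ready[-1]
    placed[i] <- TRUE
    order <- c(order, i)
    children <- which((!is.na(fa) & fa == i) | (!is.na(mo) & mo == i))
    for (ch in children) {
      indeg[ch] <- indeg[ch] - sum(c(fa[ch], mo[ch]) == i, na.rm = TRUE)
      if (indeg[ch] == 0L && !placed[ch]) ready <- c(ready, ch)
    }
  }
  if (length(order) < n)
    stop("cycle in parentage involving: ",
         paste(ped$id[!placed], collapse = ", "))
  order
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("<pedigree> %d members (%d founders, %d affected, %d genotyped)\n",
              nrow(x), sum(is_founder(x)), sum(x$affected == "yes"),
              sum(x$genotyped)))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Founder indicator
#' @param ped a [pedigree()].
#' @return logical vector, `TRUE` for members with no parents in the pedigree.
#' @export
is_founder <- function(ped) is.na(ped$father)

#' @rdname is_founder
#' @export
founders <- function(ped) ped$id[is_founder(ped)]

#' @rdname is_founder
#' @export
nonfounders <- function(ped) {
  ord <- attr(ped, "topo")
  ids <- ped$id[ord]
  ids[!is_founder(ped)[ord]]
}

#' Read a pedigree from a PED file
#'
#' Reads the whitespace-separated 6-column PED dialect
#' (family, individual, father, mother, sex, phenotype). `0` denotes a
#' missing parent; sex is coded 1 = male, 2 = female, other = unknown;
#' phenotype 2 = affected, 1 = unaffected, 0 / -9 = unknown.
#'
#' @param path path to a PED file.
#' @param family family identifier to extract when the file holds several
#'   families; by default the file must contain exactly one.
#' @param genotyped optional character vector of ids flagged as genotyped;
#'   by default all members are (PED carries no such flag).
#' @return a [pedigree()].
#' @export
read_pedigree <- function(path, family = NULL, genotyped = NULL) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 6) stop("PED file must have at least 6 columns")
  names(tab)[1:6] <- c("fam", "id", "father", "mother", "sex", "phen")
  if (is.null(family)) {
    fams <- unique(tab$fam)
    if (length(fams) > 1)
      stop("file contains ", length(fams), " families; pass `family=`")
    family <- fams
  }
  tab <- tab[tab$fam == family, , drop = FALSE]
  if (!nrow(tab)) stop("family '", family, "' not found")
  sex <- c("1" = "male", "2" = "female")[tab$sex]
  sex[is.na(sex)] <- "unknown"
  aff <- c("2" = "yes", "1" = "no")[tab$phen]
  aff[is.na(aff)] <- "unknown"
  g <- if (is.null(genotyped)) TRUE else tab$id %in% genotyped
  pedigree(id = tab$id, father = tab$father, mother = tab$mother,
           sex = sex, affected = aff, genotyped = g, family = family)
}

#' Write a pedigree as a PED file
#' @param ped a [pedigree()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  out <- data.frame(
    fam = attr(ped, "family"),
    id = ped$id,
    father = ifelse(is.na(ped$father), "0", ped$father),
    mother = ifelse(is.na(ped$mother), "0", ped$mother),
    sex = c(male = "1", female = "2", unknown = "0")[ped$sex],
    phen = c(yes = "2", no = "1", unknown = "0")[ped$affected]
  )
  utils::write.table(out, path, quote = FALSE, sep = " ",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' The package's reference multiplex pedigree
#'
#' A three-generation multiplex family with five affected members: four
#' affected full siblings (II.2-II.5, children of founders I.1 x I.2) and one
#' affected grandchild (III.5, child of II.5 and a married-in founder).
#' An unaffected grandchild III.3 (child of II.2 and a married-in founder)
#' is also genotyped. With six non-founders the inheritance-vector space has
#' 12 meiosis bits, and the probability that all four siblings share both
#' parental alleles identical-by-descent is 1/64, so the maximum attainable
#' Kong-Cox exponential LOD for this family is log10(64) = 1.806.
#'
#' @param genotyped ids with genotype data; the default is the seven members
#'   used for linkage (one founder parent, the four affected siblings, and
#'   the two genotyped grandchildren).
#' @return a [pedigree()].
#' @export
multiplex_pedigree <- function(genotyped = c("I.2", "II.2", "II.3", "II.4",
                                             "II.5", "III.3", "III.5")) {
  ids <- c("I.1", "I.2", "II.1", "II.2", "II.3", "II.4", "II.5", "II.6",
           "III.3", "III.5")
  pedigree(
    id = ids,
    father = c(NA, NA, NA, "I.1", "I.1", "I.1", "I.1", NA, "II.2", "II.5"),
    mother = c(NA, NA, NA, "I.2", "I.2", "I.2", "I.2", NA, "II.1", "II.6"),
    sex = c("male", "female", "female", "male", "male", "female", "male",
            "female", "unknown", "unknown"),
    affected = c("no", "no", "no", "yes", "yes", "yes", "yes", "no",
                 "no", "yes"),
    genotyped = ids %in% genotyped,
    family = "INDEX"
  )
}

#' Pedigree kinship matrix
#'
#' Recursive kinship coefficients phi(i, j): founders are assumed non-inbred
#' and mutually unrelated, so phi(i, i) = 1/2 and, processing descendants
#' after ancestors, phi(i, j) = (phi(father_i, j) + phi(mother_i, j)) / 2.
#' Twice this matrix scales additive genotype covariance between relatives.
#'
#' @param ped a [pedigree()].
#' @return symmetric numeric matrix with dimnames = individual ids.
#' @export
kinship_matrix <- function(ped) {
  n <- nrow(ped)
  ord <- attr(ped, "topo")
  fa <- match(ped$father, ped$id)
  mo <- match(ped$mother, ped$id)
  phi <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in ord) {
    if (is.na(fa[i])) {
      phi[i, i] <- 0.5
    } else {
      # ancestors already processed (topological order)
      prev <- ord[seq_len(which(ord == i) - 1L)]
      phi[i, prev] <- (phi[fa[i], prev] + phi[mo[i], prev]) / 2
      phi[prev, i] <- phi[i, prev]
      phi[i, i] <- 0.5 + phi[fa[i], mo[i]] / 2
    }
  }
  phi
}
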