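# Elemental formulas, nuclide data, the SMX fragment/isotopologue catalog,
# and label / isotope mass-balance arithmetic.

#' Nuclide masses and natural abundances
#'
#' Returns the table of exact nuclide masses (u) and natural isotopic
#' abundances (atom fractions) used throughout the package, together with the
#' electron mass. Values are standard published nuclide data (AME/CIAAW,
#' truncated to the precision relevant at R = 90,000). Abundances of each
#' element's isotopes sum to 1 within 1e-6.
#'
#' @return A list with elements `isotopes` (a data.frame with columns
#'   `element`, `mass_number`, `mass`, `abundance`) and `electron_mass` (u).
#' @export
#' @examples
#' tab <- isotope_table()
#' subset(tab$isotopes, element == "C")
isotope_table <- function() {
  iso <- data.frame(
    element = c("H", "H",
                "C", "C",
                "N", "N",
                "O", "O", "O",
                "S", "S", "S", "S"),
    mass_number = c(1L, 2L, 12L, 13L, 14L, 15L, 16L, 17L, 18L,
                    32L, 33L, 34L, 36L),
    mass = c(1.0078250319, 2.0141017781,
             12.0, 13.0033548378,
             14.0030740052, 15.0001088984,
             15.9949146221, 16.9991315000, 17.9991604000,
             31.9720706900, 32.9714585000, 33.9678668300, 35.9670808800),
    abundance = c(0.999885, 0.000115,
                  0.9893, 0.0107,
                  0.996337, 0.003663,
                  0.99757, 0.00038, 0.00205,
                  0.9499, 0.0075, 0.0425, 0.0001),
    stringsAsFactors = FALSE
  )
  ab <- tapply(iso$abundance, iso$element, sum)
  stopifnot(all(abs(ab - 1) < 1e-6))
  list(isotopes = iso, electron_mass = 0.000548579909)
}

#' Parse a chemical formula in Hill notation
#'
#' @param x Formula string, e.g. `"C6H6N"` or `"C10H11N3O3S"`.
#' @return Named integer vector of atom counts.
#' @export
#' @examples
#' parse_formula("C4H7N2O")
parse_formula <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, nzchar(x))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", x)[[1]]
  toks <- regmatches(x, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(x))
    stop("cannot parse formula: ", x)
  el <- sub("[0-9]+$", "", toks)
  n <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", toks)))
  n[is.na(n)] <- 1L
  counts <- tapply(n, el, sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  if (any(out < 0) || sum(out) == 0L)
    stop("formula must contain at least one atom")
  out
}

as_formula <- function(x) {
  if (is.character(x)) return(parse_formula(x))
  stopifnot(is.numeric(x), !is.null(names(x)), all(x >= 0), sum(x) > 0)
  y <- as.integer(x)
  names(y) <- names(x)
  y
}

#' Define an isotopologue of a fragment ion
#'
#' An isotopologue spec couples a fragment ion's elemental formula with an
#' isotope substitution (e.g. one 13-C replacing a 12-C), a positive charge,
#' and the text label used for it in scan tables.
#'
#' @param fragment Fragment name, e.g. `"F92"`.
#' @param formula Formula string or named count vector (the all-light ion).
#' @param substitutions Named list mapping element symbol to
#'   `c(mass_number, count)`, e.g. `list(C = c(13, 1))`. Empty list for the
#'   unsubstituted (base peak) species.
#' @param charge Positive integer charge.
#' @param label Text key identifying this species in scan tables; defaults to
#'   the fragment name plus the substitution.
#' @return An object of class `iso_spec`.
#' @export
iso_spec <- function(fragment, formula, substitutions = list(), charge = 1L,
                     label = NULL) {
  f <- as_formula(formula)
  if (!(is.numeric(charge) && length(charge) == 1L && charge >= 1))
    stop("charge must be a positive integer (charge >= 1)")
  for (el in names(substitutions)) {
    sub <- substitutions[[el]]
    stopifnot(length(sub) == 2L, sub[2] >= 1)
    if (!el %in% names(f) || sub[2] > f[[el]])
      stop("substitution count for ", el, " exceeds formula count")
  }
  if (is.null(label)) {
    if (length(substitutions) == 0L) {
      label <- fragment
    } else {
      el <- names(substitutions)[1]
      label <- paste0(fragment, " ", substitutions[[el]][1], el)
    }
  }
  structure(
    list(fragment = fragment, formula = f, substitutions = substitutions,
         charge = as.integer(charge), label = label),
    class = "iso_spec"
  )
}

#' @export
print.iso_spec <- function(x, ...) {
  cat(sprintf("<iso_spec %s: %s, z=%d>\n", x$label,
              paste0(names(x$formula), x$formula, collapse = ""), x$charge))
  invisible(x)
}

#' Theoretical mass-to-charge ratio of an isotopologue
#'
#' Sums exact atomic masses with the heavy-isotope substitutions applied and
#' subtracts one electron mass per positive charge.
#'
#' @param spec An [iso_spec()].
#' @param table Nuclide table from [isotope_table()].
#' @return m/z in u per elementary charge.
#' @export
#' @examples
#' monoisotopic_mz(iso_spec("F92", "C6H6N"))  # ~92.0495
monoisotopic_mz <- function(spec, table = isotope_table()) {
  stopifnot(inherits(spec, "iso_spec"))
  iso <- table$isotopes
  mass_of <- function(element, mass_number = NULL) {
    rows <- iso[iso$element == element, , drop = FALSE]
    if (nrow(rows) == 0L) stop("unknown element in nuclide table: ", element)
    if (is.null(mass_number)) {
      # lightest (principal) isotope
      rows$mass[which.max(rows$abundance)]
    } else {
      hit <- rows[rows$mass_number == mass_number, , drop = FALSE]
      if (nrow(hit) == 0L)
        stop("unknown nuclide: ", mass_number, element)
      hit$mass[1]
    }
  }
  total <- 0
  for (el in names(spec$formula)) {
    n <- spec$formula[[el]]
    n_sub <- 0L
    if (el %in% names(spec$substitutions)) {
      sub <- spec$substitutions[[el]]
      n_sub <- as.integer(sub[2])
      total <- total + n_sub * mass_of(el, sub[1])
    }
    total <- total + (n - n_sub) * mass_of(el)
  }
  (total - spec$charge * table$electron_mass) / spec$charge
}

#' Assign an observed m/z to a catalog isotopologue
#'
#' @param observed_mz Observed m/z value.
#' @param catalog List of [iso_spec()] objects.
#' @param tolerance_ppm Match tolerance in parts per million (> 0).
#' @param table Nuclide table.
#' @return The matching `iso_spec`, or `NULL` if none lies within tolerance.
#'   Two catalog entries within tolerance is an ambiguity error.
#' @export
match_peak <- function(observed_mz, catalog, tolerance_ppm = 20,
                       table = isotope_table()) {
  stopifnot(tolerance_ppm > 0, length(observed_mz) == 1L)
  mzs <- vapply(catalog, monoisotopic_mz, numeric(1), table = table)
  ppm <- abs(mzs - observed_mz) / mzs * 1e6
  hits <- which(ppm <= tolerance_ppm)
  if (length(hits) == 0L) return(NULL)
  if (length(hits) > 1L) {
    labs <- vapply(catalog[hits], `[[`, character(1), "label")
    stop("ambiguous peak match at m/z ", observed_mz, ": ",
         paste(labs, collapse = ", "))
  }
  catalog[[hits]]
}

#' Singly-substituted isotopologue ratio under the stochastic model
#'
#' Under a stochastic (independent, uniform) distribution of heavy isotopes
#' across equivalent positions, the abundance ratio of the singly heavy-
#' substituted isotopologue to the unsubstituted one is the per-atom isotope
#' ratio multiplied by the number of atoms of that element. This is what lets
#' an isotopologue ratio stand in for an element's isotope ratio.
#'
#' @param formula Formula string or named count vector.
#' @param element Element symbol present in the formula.
#' @param per_atom_ratio Heavy/light isotope ratio per atom (> 0).
#' @return Expected isotopologue abundance ratio.
#' @export
#' @examples
#' stochastic_isotopologue_ratio("C6H6N", "C", 0.0108) # 6 x 0.0108
stochastic_isotopologue_ratio <- function(formula, element, per_atom_ratio) {
  f <- as_formula(formula)
  if (!element %in% names(f) || f[[element]] == 0L)
    stop("element ", element, " absent from formula")
  stopifnot(per_atom_ratio > 0)
  f[[element]] * per_atom_ratio
}

#' Natural heavy/light isotope ratio of an element
#'
#' Ratio of the most abundant heavy isotope to the principal isotope
#' (13C/12C, 15N/14N, ...), from the nuclide table. Used as the default
#' per-atom ratio in mixing and simulation arithmetic; overridable there.
#'
#' @param element Element symbol.
#' @param table Nuclide table.
#' @return Dimensionless isotope ratio.
#' @export
natural_isotope_ratio <- function(element, table = isotope_table()) {
  rows <- table$isotopes[table$isotopes$element == element, , drop = FALSE]
  if (nrow(rows) < 2L) stop("no heavy isotope tabulated for ", element)
  rows <- rows[order(rows$mass_number), ]
  major <- rows$abundance[which.max(rows$abundance)]
  heavy <- rows$abundance[which.max(rows$abundance) + 1L]
  heavy / major
}

#' Position-specific enrichment from mixing labeled and unlabeled material
#'
#' Computes the delta-scale enrichment at a single labeled position obtained
#' by spiking a small amount of isotopically labeled compound into unlabeled
#' compound. Atom fractions at the labeled position are mixed mole-weighted,
#' converted to isotope ratios R = x/(1-x), and compared with the natural
#' ratio. Labeled and unlabeled material are treated as isobaric (one shared
#' molar mass), so mole amounts may be given as masses.
#'
#' @param labeled_moles,unlabeled_moles Amounts (moles or, equivalently,
#'   masses) of labeled and unlabeled compound, both > 0.
#' @param label_atom_fraction Heavy-isotope atom fraction at the labeled
#'   position in the labeled material, in (0, 1). E.g. 0.99 for a 99 atom %
#'   product.
#' @param natural_atom_fraction Natural heavy-isotope atom fraction, in
#'   (0, 1). Default 0.0107 (13C).
#' @return Enrichment at the labeled position in per mil.
#' @export
#' @examples
#' # 1 mg of 99 atom % 13C product into 1 g natural material: ~90-100 permil
#' position_enrichment_from_mixing(0.001, 1, 0.99, 0.0107)
position_enrichment_from_mixing <- function(labeled_moles, unlabeled_moles,
                                            label_atom_fraction,
                                            natural_atom_fraction = 0.0107) {
  stopifnot(labeled_moles > 0, unlabeled_moles > 0,
            label_atom_fraction > 0, label_atom_fraction < 1,
            natural_atom_fraction > 0, natural_atom_fraction < 1)
  if (label_atom_fraction <= natural_atom_fraction)
    warning("label atom fraction <= natural abundance: depletion standard")
  w <- labeled_moles / (labeled_moles + unlabeled_moles)
  x_mix <- w * label_atom_fraction + (1 - w) * natural_atom_fraction
  r_mix <- x_mix / (1 - x_mix)
  r_nat <- natural_atom_fraction / (1 - natural_atom_fraction)
  (r_mix / r_nat - 1) * 1000
}

#' Define a molecule with a fragment partition
#'
#' @param name Molecule name.
#' @param formula Formula string or named count vector.
#' @param fragments Named list: fragment name -> named atom-count vector of
#'   the molecule's atoms carried by that fragment. Per element the fragment
#'   counts must sum to at most the molecule count.
#' @return Object of class `molecule_def`.
#' @export
molecule_def <- function(name, formula, fragments) {
  f <- as_formula(formula)
  stopifnot(is.list(fragments), length(fragments) >= 1L,
            !is.null(names(fragments)))
  for (el in unique(unlist(lapply(fragments, names)))) {
    tot <- sum(vapply(fragments, function(fr)
      if (el %in% names(fr)) fr[[el]] else 0L, numeric(1)))
    if (!el %in% names(f) || tot > f[[el]])
      stop("fragment atom counts for ", el, " exceed molecule formula")
  }
  structure(list(name = name, formula = f, fragments = fragments),
            class = "molecule_def")
}

frag_count <- function(molecule, fragment_name, element) {
  if (!fragment_name %in% names(molecule$fragments))
    stop("unknown fragment: ", fragment_name)
  fr <- molecule$fragments[[fragment_name]]
  if (element %in% names(fr)) fr[[element]] else 0L
}

#' Sulfamethoxazole and its ESI fragment partition
#'
#' SMX (C10H11N3O3S) fragments under positive-mode HCD into F92
#' (the aniline part, carrying 6 C and 1 N) and F99 (the
#' 3-amino-5-methylisoxazole part, carrying 4 C, 2 N and 1 O). Together the
#' two fragments account for all 10 carbon and all 3 nitrogen atoms, so
#' fragment deltas and the compound-average delta are linked by atom-count
#' mass balance for both elements.
#'
#' @return A `molecule_def` for SMX.
#' @export
smx_molecule <- function() {
  molecule_def(
    name = "SMX",
    formula = "C10H11N3O3S",
    # hydrogen is excluded from the partition: the fragment ions gain/lose
    # protons during ionization and HCD, so ion H counts do not partition
    # the neutral molecule's H
    fragments = list(
      F92 = c(C = 6L, N = 1L),
      F99 = c(C = 4L, N = 2L, O = 1L)
    )
  )
}

#' The six monitored SMX fragment isotopologues
#'
#' The catalog of species monitored for fragment-specific C and N isotope
#' analysis of SMX: for each of F92 (C6H6N+) and F99 (C4H7N2O+), the
#' unsubstituted base peak, the singly 15N-substituted species and the singly
#' 13C-substituted species.
#'
#' @return Named list of [iso_spec()] objects keyed by scan-table label.
#' @export
#' @examples
#' sapply(smx_catalog(), monoisotopic_mz)
smx_catalog <- function() {
  specs <- list(
    iso_spec("F92", "C6H6N",  list(),              1L, "F92"),
    iso_spec("F92", "C6H6N",  list(N = c(15, 1)),  1L, "F92 15N"),
    iso_spec("F92", "C6H6N",  list(C = c(13, 1)),  1L, "F92 13C"),
    iso_spec("F99", "C4H7N2O", list(),             1L, "F99"),
    iso_spec("F99", "C4H7N2O", list(N = c(15, 1)), 1L, "F99 15N"),
    iso_spec("F99", "C4H7N2O", list(C = c(13, 1)), 1L, "F99 13C")
  )
  names(specs) <- vapply(specs, `[[`, character(1), "label")
  specs
}

# label -> (fragment, element) map for the substituted species of a catalog
catalog_pairs <- function(catalog = smx_catalog()) {
  rows <- lapply(catalog, function(sp) {
    if (length(sp$substitutions) == 0L) return(NULL)
    el <- names(sp$substitutions)[1]
    data.frame(label = sp$label, fragment = sp$fragment, element = el,
               base_label = sp$fragment, n_atoms = sp$formula[[el]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Fragment enrichment implied by a compound-average (bulk) shift
#'
#' If an isotopic label sits entirely inside one fragment and all other
#' positions stay at reference composition, a bulk delta shift measured on
#' the whole molecule maps to the fragment as
#' `shift * n_element(molecule) / n_element(fragment)` (first-order delta
#' mass balance). For SMX nitrogen and F99 this is the 3/2 factor relating
#' compound-average IRMS shifts to the reactive fragment.
#'
#' @param delta_bulk_shift Bulk delta shift in per mil.
#' @param molecule A [molecule_def()].
#' @param fragment_name Fragment carrying the label.
#' @param element Element symbol.
#' @return Fragment delta shift (per mil).
#' @export
#' @examples
#' fragment_calc_from_bulk(12, smx_molecule(), "F99", "N")  # 18
fragment_calc_from_bulk <- function(delta_bulk_shift, molecule,
                                    fragment_name, element) {
  n_frag <- frag_count(molecule, fragment_name, element)
  if (n_frag == 0L)
    stop("fragment ", fragment_name, " contains no ", element)
  n_mol <- molecule$formula[[element]]
  delta_bulk_shift * n_mol / n_frag
}

#' Compound-average delta from fragment deltas
#'
#' Atom-count-weighted mean of fragment deltas (first-order delta mass
#' balance). Requires the named fragments to partition every atom of the
#' element in the molecule.
#'
#' @param fragment_deltas Named numeric vector, fragment name -> delta (per
#'   mil).
#' @param molecule A [molecule_def()].
#' @param element Element symbol.
#' @return Bulk delta (per mil).
#' @export
#' @examples
#' bulk_from_fragments(c(F92 = 30, F99 = 0), smx_molecule(), "N")  # 10
bulk_from_fragments <- function(fragment_deltas, molecule, element) {
  stopifnot(!is.null(names(fragment_deltas)))
  n <- vapply(names(fragment_deltas), frag_count, numeric(1),
              molecule = molecule, element = element)
  n_mol <- molecule$formula[[element]]
  if (sum(n) != n_mol)
    stop("fragments cover ", sum(n), " of ", n_mol, " ", element,
         " atoms: partition incomplete")
  sum(n * fragment_deltas) / n_mol
}

# Exact ratio-space mass balance (internal oracle for tests): mixes atom
# fractions rather than deltas. delta values are per mil vs a reference of
# per-atom ratio r_ref.
bulk_from_fragments_exact <- function(fragment_deltas, molecule, element,
                                      r_ref) {
  n <- vapply(names(fragment_deltas), frag_count, numeric(1),
              molecule = molecule, element = element)
  stopifnot(sum(n) == molecule$formula[[element]])
  r <- r_ref * (1 + fragment_deltas / 1000)
  x <- r / (1 + r)                      # atom fraction per fragment
  x_bulk <- sum(n * x) / sum(n)
  r_bulk <- x_bulk / (1 - x_bulk)
  (r_bulk / r_ref - 1) * 1000
}
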