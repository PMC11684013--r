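# AnchorMap: named residue/atom selections and domain partitions, decoupled
# from file numbering. Domains use author-style per-chain residue numbering
# (e.g. NKG2A residues 1-45 = ICD); lipid metadata names the headgroup bead
# and the acyl-chain C/H naming scheme.

#' Build an AnchorMap
#'
#' @param anchors named list; each element a list of entries
#'   `list(chain=, resno=, name=)` (`name` optional: whole residue)
#' @param domains named list; each element `list(chain=, resno=)` with `resno`
#'   an integer vector of author-style residue numbers
#' @param lipids list with fields `resname` (lipid residue names), `head`
#'   (headgroup atom name), `carbon_prefix` / `hydrogen_suffixes` describing
#'   the acyl naming scheme (carbons `C1..Cn`, hydrogens `H<k>A`, `H<k>B`, ...)
#' @return object of class `AnchorMap`
#' @export
anchor_map <- function(anchors = list(), domains = list(), lipids = NULL) {
  structure(list(anchors = anchors, domains = domains, lipids = lipids),
            class = "AnchorMap")
}

#' Read an AnchorMap from a YAML (or JSON) config
#' @param path config file
#' @export
read_anchor_map <- function(path) {
  cfg <- yaml::read_yaml(path)
  am <- anchor_map(anchors = cfg$anchors %||% list(),
                   domains = lapply(cfg$domains %||% list(), function(d) {
                     if (!is.null(d$from)) d$resno <- seq(d$from, d$to)
                     d
                   }),
                   lipids = cfg$lipids)
  am
}

#' Write an AnchorMap to YAML
#' @export
write_anchor_map <- function(map, path) {
  yaml::write_yaml(unclass(map), path)
  invisible(path)
}

#' Resolve a named anchor to atom indices
#'
#' @param traj Trajectory; @param map AnchorMap; @param which anchor name
#' @return integer atom indices
#' @export
resolve_anchor <- function(traj, map, which) {
  a <- map$anchors[[which]]
  if (is.null(a)) stop("no anchor named '", which, "' in the AnchorMap")
  if (!is.null(a$chain)) a <- list(a)  # single entry shorthand
  idx <- unlist(lapply(a, function(e) {
    select_atoms(traj, chain = e$chain, resno = e$resno, name = e$name)
  }))
  idx <- sort(unique(idx))
  if (!length(idx)) stop("anchor '", which, "' matches no atom in the topology")
  idx
}

#' Resolve domain partitions to per-domain atom (or residue) indices
#'
#' Checks that domains are disjoint and, when `require_partition`, that they
#' cover every residue of the named chains exactly once.
#'
#' @param traj Trajectory; @param map AnchorMap
#' @param atoms restrict to these atom indices (e.g. a C-alpha selection)
#' @param require_partition error unless the domains tile the restricted atoms
#' @return named list of integer atom indices
#' @export
resolve_domains <- function(traj, map, atoms = NULL, require_partition = TRUE) {
  if (!length(map$domains)) stop("AnchorMap carries no domain definitions")
  out <- lapply(map$domains, function(d) {
    idx <- select_atoms(traj, chain = d$chain, resno = d$resno)
    if (!is.null(atoms)) idx <- intersect(idx, atoms)
    idx
  })
  all_idx <- unlist(out)
  if (anyDuplicated(all_idx)) stop("domain definitions overlap")
  if (require_partition && !is.null(atoms) && !setequal(all_idx, atoms)) {
    miss <- setdiff(atoms, all_idx)
    stop(length(miss), " selected atom(s) fall outside every domain ",
         "(first at topology row ", miss[1], ")")
  }
  out
}

#' Default NKG2A/CD94/HLA-E anchor map
#'
#' Encodes the receptor's domain partition (NKG2A ICD = residues 1-45, linker,
#' TMD, ECD; CD94 ICD/TMD/ECD; HLA-E as one block) and the residue anchors used
#' throughout the analysis battery: the ITIM tyrosines Tyr8/Tyr40, the TM axis
#' residues Val73/Val92, the receptor-head bending anchors Cys58-Ser110
#' (vertical) and His184-Thr126 (horizontal), the linker hydrogen-bond pair
#' Ser34(CD94)/Thr96(NKG2A), and the head-group salt-bridge residues
#' Asp106/Ser109 (CD94), Lys135/Arg137 (NKG2A), Asp149 (HLA-E). Chain labels:
#' A = NKG2A, B = CD94, C = HLA-E.
#'
#' @param nkg2a,cd94,hlae chain labels in the topology
#' @export
default_anchor_map <- function(nkg2a = "A", cd94 = "B", hlae = "C") {
  anchor_map(
    anchors = list(
      tyr8_oh    = list(chain = nkg2a, resno = 8,   name = "OH"),
      tyr40_oh   = list(chain = nkg2a, resno = 40,  name = "OH"),
      val73      = list(chain = nkg2a, resno = 73),
      val92      = list(chain = nkg2a, resno = 92),
      cys58      = list(chain = nkg2a, resno = 58),
      ser110     = list(chain = nkg2a, resno = 110),
      his184     = list(chain = nkg2a, resno = 184),
      thr126     = list(chain = nkg2a, resno = 126),
      ser34_og   = list(chain = cd94,  resno = 34,  name = "OG"),
      thr96_og1  = list(chain = nkg2a, resno = 96,  name = "OG1"),
      asp106     = list(chain = cd94,  resno = 106),
      ser109     = list(chain = cd94,  resno = 109),
      lys135     = list(chain = nkg2a, resno = 135),
      arg137     = list(chain = nkg2a, resno = 137),
      asp149     = list(chain = hlae,  resno = 149)
    ),
    domains = list(
      NKG2A_ICD    = list(chain = nkg2a, resno = 1:45),
      NKG2A_linker = list(chain = nkg2a, resno = 46:70),
      NKG2A_TMD    = list(chain = nkg2a, resno = 71:93),
      NKG2A_ECD    = list(chain = nkg2a, resno = 94:233),
      CD94         = list(chain = cd94,  resno = 1:179),
      HLA_E        = list(chain = hlae,  resno = 1:400)
    ),
    lipids = list(resname = c("POPC", "POPA", "DLPC", "DPPC", "CHL1", "LIP"),
                  head = "BD", carbon_prefix = "C",
                  hydrogen_suffixes = c("A", "B", "C"))
  )
}
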