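#' The 21-channel 10-20 recording montage
#'
#' Channel order follows the clinical recording convention: Fp2, Fp1, F8,
#' F7, F4, F3, A2, A1, T4, T3, C4, C3, T6, T5, P4, P3, O2, O1, Fz, Cz, Pz.
#'
#' @return character vector of 21 channel labels
#' @export
channels1020 <- function() {
  c("Fp2", "Fp1", "F8", "F7", "F4", "F3", "A2", "A1", "T4", "T3",
    "C4", "C3", "T6", "T5", "P4", "P3", "O2", "O1", "Fz", "Cz", "Pz")
}

# Nearest-neighbor adjacency on the 10-20 grid; symmetric, every channel has
# >= 2 neighbors. Used as unweighted Hjorth derivation sets.
.neighbors1020 <- function() {
  list(
    Fp1 = c("Fp2", "F7", "F3", "Fz"),
    Fp2 = c("Fp1", "F8", "F4", "Fz"),
    F7  = c("Fp1", "F3", "T3", "A1"),
    F8  = c("Fp2", "F4", "T4", "A2"),
    F3  = c("Fp1", "F7", "Fz", "C3"),
    F4  = c("Fp2", "F8", "Fz", "C4"),
    Fz  = c("Fp1", "Fp2", "F3", "F4", "Cz"),
    A1  = c("F7", "T3", "T5"),
    A2  = c("F8", "T4", "T6"),
    T3  = c("F7", "C3", "T5", "A1"),
    T4  = c("F8", "C4", "T6", "A2"),
    C3  = c("F3", "T3", "Cz", "P3"),
    C4  = c("F4", "T4", "Cz", "P4"),
    Cz  = c("Fz", "C3", "C4", "Pz"),
    T5  = c("T3", "P3", "O1", "A1"),
    T6  = c("T4", "P4", "O2", "A2"),
    P3  = c("C3", "T5", "Pz", "O1"),
    P4  = c("C4", "T6", "Pz", "O2"),
    Pz  = c("Cz", "P3", "P4", "O1", "O2"),
    O1  = c("T5", "P3", "Pz", "O2"),
    O2  = c("T6", "P4", "Pz", "O1")
  )
}

#' Construct a montage
#'
#' @param labels ordered channel names
#' @param neighbors named list: label -> neighbor labels; must be symmetric
#'   with at least two neighbors per channel
#' @return a [Montage-class]
#' @export
montage <- function(labels, neighbors) {
  new("Montage", labels = labels, neighbors = neighbors[labels])
}

#' Default 21-channel 10-20 montage with Hjorth neighbor sets
#'
#' @param exclude channels to drop (e.g. `c("A1","A2")` to restrict to the
#'   19 scalp positions); neighbor sets are restricted accordingly
#' @return a [Montage-class]
#' @export
montage1020 <- function(exclude = character()) {
  labs <- setdiff(channels1020(), exclude)
  nb <- lapply(.neighbors1020()[labs], function(x) setdiff(x, exclude))
  montage(labs, nb)
}

#' Read a montage neighbor table from YAML
#'
#' Expects a mapping `labels: [...]` plus `neighbors: {label: [..], ...}`.
#'
#' @param path YAML file
#' @return a [Montage-class]
#' @export
readMontage <- function(path) {
  y <- yaml::read_yaml(path)
  montage(as.character(y$labels),
          lapply(y$neighbors, as.character))
}

#' Write a montage neighbor table to YAML
#'
#' @param m a [Montage-class]
#' @param path output file
#' @return `path`, invisibly
#' @export
writeMontage <- function(m, path) {
  yaml::write_yaml(list(labels = as.list(m@labels),
                        neighbors = lapply(m@neighbors, as.list)), path)
  invisible(path)
}
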