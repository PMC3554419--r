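# three-step linear pathway S -> A -> B -> P with irreversible MM steps;
# closed form at clamped S: flux J = 10 S/(1+S), A = B = 2J/(20-J)
toy_pathway <- function(vmax = c(10, 20, 20), km = c(1, 2, 2)) {
  network_model(
    list(species("S", "extracellular"), species("A"), species("B"),
         species("P", "extracellular")),
    list(reaction("v1", c(S = -1, A = 1),
                  rate_law("irreversible_mm", vmax[1],
                           km_substrates = c(S = km[1])), 1),
         reaction("v2", c(A = -1, B = 1),
                  rate_law("irreversible_mm", vmax[2],
                           km_substrates = c(A = km[2])), 2),
         reaction("v3", c(B = -1, P = 1),
                  rate_law("irreversible_mm", vmax[3],
                           km_substrates = c(B = km[3])), 3)),
    clamped = c("S", "P"), name = "toy")
}

toy_clamp <- function(S = 9) c(S = S, P = 0)

glyco_clamp <- function(glucose = 25 / 180.16 * 1000)
  c(GLCo = glucose, ETOH = 0, GLYC = 0, CO2 = 0)

glyco_metabolites <- c("G6P", "F6P", "FBP", "TRIO", "PEP", "PYR")

# independent 1-D bisection on a monotone function
bisect <- function(f, lower, upper, tol = 1e-12, max_iter = 200L) {
  fl <- f(lower)
  for (i in seq_len(max_iter)) {
    mid <- (lower + upper) / 2
    fm <- f(mid)
    if (abs(upper - lower) < tol) return(mid)
    if (sign(fm) == sign(fl)) {
      lower <- mid; fl <- fm
    } else upper <- mid
  }
  (lower + upper) / 2
}
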