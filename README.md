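# grangerfold

Granger causality analysis of protein (un)folding trajectories.

## The problem

A long molecular dynamics trajectory of a small fast-folding protein (a
β-hairpin miniprotein such as chignolin, sampled over many reversible
folding and unfolding events) records *what* happens, but not *which*
structural rearrangements drive the process and which merely follow. Free
energy profiles and Markov state models describe states and rates; they do
not rank the temporal influence of individual interactions. `grangerfold`
fills that gap for anyone analysing equilibrium folding trajectories: it
quantifies, contact by contact, how much each inter-residue distance helps
predict the future of every other, and assembles the result into an
objective ranking of initiators and terminators of (un)folding events.

## The method

The trajectory is featurized into the K = n(n−1)/2 inter-residue minimum
heavy-atom distances, normalized to zero mean and unit variance. A
multivariate autoregressive model of order P,

    x(t) = Σ_p A_p x(t − pΔt) + Δx(t),

is fitted by the Yule–Walker method from the lagged moment matrices
Γ(r) = ⟨x(t) xᵀ(t − rΔt)⟩, giving the residual white-noise covariance
V = Γ(0) − Σ_p A_p Γ(−p); the order is selected by the Schwarz–Bayes
criterion SBC(P) = ln det V̂ + P K² ln N / N. The Granger coupling from
channel j to channel i compares V with the residual covariance V⁽ʲ⁾ of the
model refitted without channel j:

    J_{j→i} = 1 − V_i / V_i^{(j)}  ∈ [0, 1],

0 meaning channel j carries no predictive information about i, 1 meaning
prediction of i collapses without j. Per-contact descriptors summarize the
K×K matrix: predictability to G⁻ᵢ = Σ_k J_{k→i}, predictability from
G→ᵢ = Σ_k J_{i→k}, origin predictability G°ᵢ = G→ᵢ − G⁻ᵢ (positive for
initiators, negative for terminators), and the predictability indicator
G⁺ᵢ = G→ᵢ + G⁻ᵢ. Split-half convergence and a frame-shuffle Student-t
significance test guard against overinterpretation.

A companion toolchain builds the interpretive scaffolding: TICA reaction
coordinates with kinetic mapping, validated by the transition-path
probability criterion p(TP|ξ) (diffusive limit 0.5), potential-of-mean-force
profiles, a six-state discretization with medoid representative structures,
median-filtered transition matrices, committor functions, folding-event
statistics, and the native-ensemble distance overlap Ω(ξ). Synthetic
generators (stationary VAR processes, a two-state toy folder with a planted
causal ordering, miniature polypeptide trajectories) provide ground truth
for every stage.

## Worked example

A 2×10⁵-frame toy-folder trajectory with six distance-like channels, two
switching at the barrier top (±0.15) and four inside the wells (±0.6,
±0.85):

```r
library(grangerfold)
spec <- toy_folder_spec(length = 2e5, seed = 101)
toy  <- simulate_toy_folder(spec)

# reaction-coordinate quality: p(TP|xi) against the 0.5 diffusive limit
prof <- p_tp_profile(toy$coordinate, toy_folder_cores())
cat("max p(TP|xi):", round(attr(prof, "maximum"), 3), "over",
    nrow(attr(prof, "tp_segments")), "transition paths\n")

# Granger analysis
norm <- normalize_channels(toy$channels)
desc <- gc_descriptors(gc_matrix(norm, 1), toy_folder_categories(spec))
print(desc[order(-desc$g_origin), ], digits = 3)
```

prints

```
max p(TP|xi): 0.575 over 48 transition paths
  channel   g_in  g_out g_origin g_total category
3  s-0.15 0.1420 0.1683  0.02632   0.310  barrier
4  s+0.15 0.1474 0.1645  0.01710   0.312  barrier
2  s-0.60 0.1154 0.1249  0.00945   0.240     well
5  s+0.60 0.1186 0.1280  0.00940   0.247     well
6  s+0.85 0.0976 0.0679 -0.02969   0.165     well
1  s-0.85 0.0964 0.0638 -0.03257   0.160     well
```

The hidden coordinate is a nearly ideal reaction coordinate (profile
maximum close to 0.5), and the descriptor table recovers the planted causal
structure: barrier-top channels score highest on G° (initiators of
transitions) and on overall involvement G⁺, while channels that only change
deep inside a well sit at the negative end of the G° spectrum
(terminators). The full pipeline — featurization, TICA, coordinate
validation, state/pathway characterization, Granger analysis, report — runs
from a single configuration via `run_pipeline(pipeline_config(input =
"toy"), "workdir")`.

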