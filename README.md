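# psbind

Tools for analysing how proteins bind phosphorothioate (PS) antisense
oligonucleotides, for structural biologists and nucleic-acid chemists
working on ASO-protein interactions. PS backbones — in which one
non-bridging phosphate oxygen is replaced by sulfur — dramatically
increase the protein affinity of therapeutic oligonucleotides, and each
PS linkage is a stereocentre (Rp or Sp). psbind implements the two
quantitative analyses this field runs on such systems:

1. **Solution binding.** Fluorescence-anisotropy titrations are fitted
   to the 1:1 isotherm extended with a noncompetitive nonspecific term:

   A = A₀ + ΔA · (Prot_RNA + NS·Prot_tot) / RNA_tot

   where Prot_RNA solves K_D·Prot_RNA = (Prot_tot(1−NS) − Prot_RNA)
   (RNA_tot − Prot_RNA), the physical root of the binding quadratic.
   Replicates are fitted globally with shared (K_D, A₀, ΔA, NS); the
   hypothesis NS > 0 is tested against NS = 0 by the least-squares AIC,
   n·ln(RSS/n) + 2k; outliers are screened once by studentized
   residuals (|r| > 3) and the reduced set refitted.

2. **Stereochemistry.** PS linkages are extracted from PDB/mmCIF
   models; Rp/Sp configurations are assigned from coordinates by CIP
   priorities (S > O3′ > O5′ > O non-bridging); sulfur anomalous
   difference map peaks are measured at the two candidate non-bridging
   sites and each linkage is called Rp / Sp / mixed / indeterminate
   (3.5σ contour, 1.5× dominance margin, mean-B ≤ 60 Å² reliability
   filter).

Supporting machinery: Bondi-radius van der Waals contact detection and
PS-sulfur pocket ranking, water-bridge detection, Kabsch superposition
with iterative outlier rejection, CCP4/MRC map IO, and seeded
synthetic-data generators (titration tables, idealized PS-DNA strands
with programmed stereochemistry, matching anomalous maps) so the whole
pipeline is testable without downloads.

## Worked example

```r
library(psbind)

# --- binding: simulate a triplicate titration and refit it ---------------
truth <- binding_params(k_d = 9.3, a0 = 0.10, da = 0.15, ns = 2e-4)
series <- simulate_titration(truth, noise_sd = 0.003, seed = 42,
                             oligo = "malat-like", condition = "Ca2+")
res <- fit_binding(series, ns = "auto")
print(res$fit)
#> binding_fit (NS free, converged): n = 36, RSS = 0.0004468, AIC = -396.69
#>   K_D = 9.324 +/- 0.89 uM
#>   A0  = 0.09976 +/- 0.0012
#>   dA  = 0.1507 +/- 0.006
#>   NS  = 0.0002028 +/- 2.5e-05
res$decision$delta_aic
#> [1] -46.13
```

The fitted K_D (9.32 ± 0.89 uM) recovers the generating 9.3 uM; the
negative ΔAIC says the nonspecific term is warranted for these data,
as it should be since the truth had NS > 0.

```r
# --- stereochemistry: programmed strand -> synthetic map -> calls --------
spec <- fixture_spec(8, c("Rp", "Rp", "mixed", "Sp", "Rp", "mixed", "Sp"))
model <- build_ps_strand(spec)
map <- render_anomalous_map(model, noise = 0.3, seed = 42)
calls <- call_strand(map, model)
calls[, c("linkage_id", "call", "peak_Rp_sigma", "peak_Sp_sigma")]
#>   linkage_id  call peak_Rp_sigma peak_Sp_sigma
#> 1          1    Rp     8.0617863     0.7095288
#> 2          2    Rp     7.9303944     0.7075796
#> 3          3 mixed     3.9887462     3.7967338
#> 4          4    Sp     0.7390000     8.0198014
#> 5          5    Rp     8.0710448     0.7615369
#> 6          6 mixed     3.8842609     4.0930375
#> 7          7    Sp     0.6293539     7.6367956
```

Every programmed configuration is recovered: single-configuration sites
show one dominant peak (~8σ vs ~0.7σ), mixed sites show two
half-height peaks (~4σ each, within the dominance margin).

## Analysis workflow

The `analysis/` directory holds numbered drivers that reproduce the
package's full analysis on synthetic data, writing tables under
`results/`:

| script | what it does | output |
|---|---|---|
| `01_make_fixtures.R` | seeded strand + map + titration fixtures | `results/fixtures/` |
| `02_fit_binding.R` | global fits + AIC for a 6-system oligo panel | `results/binding_fits.csv` |
| `03_stereo_calls.R` | per-linkage stereo calls vs programmed truth | `results/stereo_calls.csv` |
| `04_structure_comparison.R` | superposition protocol + PS pocket contacts | `results/superposition.json`, `results/contact_pocket.csv` |
| `05_report.R` | combined markdown report | `results/report.md` |

Run them in order with `Rscript analysis/01_make_fixtures.R` etc.

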