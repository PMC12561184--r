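Reconstructed trial worked-example inputs
-----------------------------------------

The patient-level clinical data of the dose-escalation trial these tables
describe were never published; only summary tables were. Both files are
synthetic reconstructions: patient-level assignments chosen so that the
package's summarisation functions reproduce the published summary numbers
exactly.

teae_listing_reconstructed.csv
  One row per (patient, adverse-event term) at the patient's worst grade.
  Aggregating with teae_summary(..., n_patients = 11) reproduces the
  published safety table (e.g. white blood cell count decreased 5/11 =
  45.5%, any-grade 9/11 = 81.8%, grade >= 3 in 2/11 = 18.2%).

lesions_reconstructed.csv
  Target-lesion sums (mm) per patient and visit (month 0 = baseline)
  across the four lenvatinib dose groups (4/8/12/16 mg). Calling
  call_responses() then efficacy_table() yields 0 CR, 4 PR (one per dose
  group), 4 SD, 3 PD: ORR 36.4% (4/11) and DCR 72.7% (8/11).
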