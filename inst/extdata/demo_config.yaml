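# Demo pipeline configuration: a reduced synthetic study (spectra with the
# planted C1/C5/C12 band effects, a water reference, and paired emPAI
# tables) through classification, aquaphotomics and proteomics.
seed: 42
simulate:
  spectra:
    n_passed: 12
    n_failed: 12
    replicates_per_sample: 5
  water_scans: 10
  proteins:
    n_shared: 69
    n_unique_passed: 149
    n_unique_failed: 169
    samples_per_group: 9
preprocess:
  lo_nm: 1300
  hi_nm: 1600
  average_replicates: yes
classify:
  variance_threshold: 0.9999
aquagram: yes
proteomics:
  alpha: 0.05
  method: welch
  top_n: 20
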