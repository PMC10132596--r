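76db3a739b994539c3eed13fcb38858b  praziquantel_boundaries.csv
f0d542bf8daa3e68a86071dee6e85f09  praziquantel_calibration.csv
1583f7d01d45b6e88eac0c9b0789d07d  praziquantel_validation.csv
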