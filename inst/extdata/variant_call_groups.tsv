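group	kind	feature
Disease	onehot	disease_breast
Disease	onehot	disease_colorectal
Disease	onehot	disease_glioblastoma
Disease	onehot	disease_gst
Disease	onehot	disease_lung
Disease	onehot	disease_lymphoma
Disease	onehot	disease_melanoma
Disease	onehot	disease_ovarian
Disease	onehot	disease_pancreatic
Reviewer	onehot	reviewer_1
Reviewer	onehot	reviewer_2
Reviewer	onehot	reviewer_3
Reviewer	onehot	reviewer_4
Normal_pro	numeric	normal_VAF
Normal_pro	numeric	normal_depth
Normal_pro	numeric	normal_other_bases_count
Normal_ref	numeric	normal_ref_count
Normal_ref	numeric	normal_ref_avg_basequality
Normal_ref	numeric	normal_ref_avg_mapping_quality
Normal_ref	numeric	normal_ref_avg_pos_as_fraction
Normal_ref	numeric	normal_ref_avg_num_mismatches_as_fraction
Normal_ref	numeric	normal_ref_avg_sum_mismatch_qualities
Normal_ref	numeric	normal_ref_num_q2_containing_reads
Normal_ref	numeric	normal_ref_avg_distance_to_q2_start_in_q2_reads
Normal_ref	numeric	normal_ref_avg_clipped_length
Normal_ref	numeric	normal_ref_avg_distance_to_effective_3p_end
Normal_ref	numeric	normal_ref_num_minus_strand
Normal_ref	numeric	normal_ref_num_plus_strand
Normal_ref	numeric	normal_ref_fraction_high_quality_reads
Normal_var	numeric	normal_var_count
Normal_var	numeric	normal_var_avg_basequality
Normal_var	numeric	normal_var_avg_mapping_quality
Normal_var	numeric	normal_var_avg_pos_as_fraction
Normal_var	numeric	normal_var_avg_num_mismatches_as_fraction
Normal_var	numeric	normal_var_avg_sum_mismatch_qualities
Normal_var	numeric	normal_var_num_q2_containing_reads
Normal_var	numeric	normal_var_avg_distance_to_q2_start_in_q2_reads
Normal_var	numeric	normal_var_avg_clipped_length
Normal_var	numeric	normal_var_avg_distance_to_effective_3p_end
Normal_var	numeric	normal_var_num_minus_strand
Normal_var	numeric	normal_var_num_plus_strand
Normal_var	numeric	normal_var_fraction_high_quality_reads
Tumor_pro	numeric	tumor_VAF
Tumor_pro	numeric	tumor_depth
Tumor_pro	numeric	tumor_other_bases_count
Tumor_ref	numeric	tumor_ref_count
Tumor_ref	numeric	tumor_ref_avg_basequality
Tumor_ref	numeric	tumor_ref_avg_mapping_quality
Tumor_ref	numeric	tumor_ref_avg_pos_as_fraction
Tumor_ref	numeric	tumor_ref_avg_num_mismatches_as_fraction
Tumor_ref	numeric	tumor_ref_avg_sum_mismatch_qualities
Tumor_ref	numeric	tumor_ref_num_q2_containing_reads
Tumor_ref	numeric	tumor_ref_avg_distance_to_q2_start_in_q2_reads
Tumor_ref	numeric	tumor_ref_avg_clipped_length
Tumor_ref	numeric	tumor_ref_avg_distance_to_effective_3p_end
Tumor_ref	numeric	tumor_ref_num_minus_strand
Tumor_ref	numeric	tumor_ref_num_plus_strand
Tumor_ref	numeric	tumor_ref_fraction_high_quality_reads
Tumor_var	numeric	tumor_var_count
Tumor_var	numeric	tumor_var_avg_basequality
Tumor_var	numeric	tumor_var_avg_mapping_quality
Tumor_var	numeric	tumor_var_avg_pos_as_fraction
Tumor_var	numeric	tumor_var_avg_num_mismatches_as_fraction
Tumor_var	numeric	tumor_var_avg_sum_mismatch_qualities
Tumor_var	numeric	tumor_var_num_q2_containing_reads
Tumor_var	numeric	tumor_var_avg_distance_to_q2_start_in_q2_reads
Tumor_var	numeric	tumor_var_avg_clipped_length
Tumor_var	numeric	tumor_var_avg_distance_to_effective_3p_end
Tumor_var	numeric	tumor_var_num_minus_strand
Tumor_var	numeric	tumor_var_num_plus_strand
Tumor_var	numeric	tumor_var_fraction_high_quality_reads
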