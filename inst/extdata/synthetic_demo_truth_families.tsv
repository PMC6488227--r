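family_id	role	spread_used	n_targets
miR-001	broad	6	24
miR-002	narrow	2	24
miR-003	decoy	NA	24
miR-004	decoy	NA	24
miR-005	decoy	NA	24
miR-006	decoy	NA	24
miR-007	decoy	NA	24
miR-008	decoy	NA	24
miR-009	decoy	NA	24
miR-010	decoy	NA	24
miR-011	decoy	NA	24
miR-012	decoy	NA	24
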