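gold_id	set	mismatch	members
gold1	gold	NA	YDR255C YCL039W YIL017C YGL227W YBR105C YIL097W YMR135C
gold1	pred_a	3	YDR255C YIL017C YBR105C YIL097W YKR059W YBL080C
gold1	pred_b	2	YDR255C YCL039W YIL017C YGL227W YBR105C YMR135C YBR198C YDR252W
gold1	pred_c	1	YDR255C YCL039W YIL017C YGL227W YBR105C YIL097W YMR135C YDL176W
gold2	gold	NA	YER068W YPR072W YIL038C YCR093W YDL165W
gold2	pred_a	2	YER068W YPR072W YCR093W YCR009C YDR519W
gold2	pred_b	3	YER068W YPR072W YIL038C YCR093W YLR330W YJL203W YDR502C
gold2	pred_c	1	YER068W YPR072W YIL038C YCR093W YMR099C
gold3	gold	NA	YDL084W YDR138W YML062C YHR167W YNL139C YNL253W YDR381W
gold3	pred_a	3	YDL084W YML062C YHR167W YNL139C YEL026W
gold3	pred_b	2	YDL084W YDR138W YML062C YHR167W YDR381W YGR030C YER164W
gold3	pred_c	1	YDL084W YDR138W YML062C YHR167W YNL139C YDR381W
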