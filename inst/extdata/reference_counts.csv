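group,n_users,n_posts,n_comments,n_schedule_comments,aefi_users,aefi_positive,aefi_negative,url_users,interaction_users
RSU,6884,2940,123969,8613,1708,431,1277,1711,1004
ASU,10131,5460,157008,15980,2442,356,2086,2421,1731
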