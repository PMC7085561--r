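subject_id,test_code,method,value
1,chair_stand,manual,14
2,chair_stand,manual,15
3,chair_stand,manual,12
4,chair_stand,manual,14
5,chair_stand,manual,10
6,chair_stand,manual,16
7,chair_stand,manual,12
1,chair_stand,sensor,12
2,chair_stand,sensor,13
3,chair_stand,sensor,12
4,chair_stand,sensor,13
5,chair_stand,sensor,8
6,chair_stand,sensor,13
7,chair_stand,sensor,9
1,arm_curl,manual,23
2,arm_curl,manual,16
3,arm_curl,manual,15
4,arm_curl,manual,20
5,arm_curl,manual,14
6,arm_curl,manual,16
7,arm_curl,manual,15
1,arm_curl,sensor,22
2,arm_curl,sensor,15
3,arm_curl,sensor,15
4,arm_curl,sensor,20
5,arm_curl,sensor,14
6,arm_curl,sensor,15
7,arm_curl,sensor,13
1,two_min_step,manual,75
2,two_min_step,manual,80
3,two_min_step,manual,93
4,two_min_step,manual,97
5,two_min_step,manual,72
6,two_min_step,manual,74
7,two_min_step,manual,85
1,two_min_step,sensor,69
2,two_min_step,sensor,76
3,two_min_step,sensor,83
4,two_min_step,sensor,87
5,two_min_step,sensor,66
6,two_min_step,sensor,67
7,two_min_step,sensor,78
1,sit_reach,manual,-1
2,sit_reach,manual,3
3,sit_reach,manual,5
4,sit_reach,manual,-3
5,sit_reach,manual,2.5
6,sit_reach,manual,2
7,sit_reach,manual,-2
1,sit_reach,sensor,-1
2,sit_reach,sensor,3.5
3,sit_reach,sensor,5
4,sit_reach,sensor,-2.5
5,sit_reach,sensor,3
6,sit_reach,sensor,2
7,sit_reach,sensor,-2
1,back_scratch,manual,-3.5
2,back_scratch,manual,1
3,back_scratch,manual,2
4,back_scratch,manual,-2.5
5,back_scratch,manual,2.5
6,back_scratch,manual,-1
7,back_scratch,manual,-4
1,back_scratch,sensor,-3
2,back_scratch,sensor,1.5
3,back_scratch,sensor,2.5
4,back_scratch,sensor,-2
5,back_scratch,sensor,2.5
6,back_scratch,sensor,-1
7,back_scratch,sensor,-3.5
1,up_and_go,manual,5.3
2,up_and_go,manual,6.2
3,up_and_go,manual,3.5
4,up_and_go,manual,4.1
5,up_and_go,manual,6.1
6,up_and_go,manual,3.3
7,up_and_go,manual,6
1,up_and_go,sensor,5
2,up_and_go,sensor,6.4
3,up_and_go,sensor,3.6
4,up_and_go,sensor,4.5
5,up_and_go,sensor,5.4
6,up_and_go,sensor,3.5
7,up_and_go,sensor,6.2
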